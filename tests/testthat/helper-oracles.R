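# Independent brute-force oracles used to validate the package's fast paths.
# Everything here is deliberately written without reusing package internals.

# Interior distances (mm) of all foreground voxels to the nearest background
# voxel centre, by exhaustive search. The search set can be restricted to
# background voxels 6-adjacent to the foreground without loss: if the
# nearest background voxel b to a foreground voxel f were not adjacent to
# any foreground voxel, stepping b one voxel toward f along any axis where
# they differ stays background (else b is adjacent to foreground) and is
# strictly closer to f, contradicting minimality.
oracle_interior_distance <- function(mask, spacing) {
  dims <- dim(mask)
  fg <- which(mask)
  bg <- !mask
  pad_shift <- function(a, axis, by) {
    out <- array(FALSE, dim = dims)
    idx_src <- lapply(dims, seq_len)
    idx_dst <- idx_src
    n <- dims[axis]
    if (by == 1L) {
      idx_src[[axis]] <- seq_len(n - 1L); idx_dst[[axis]] <- 2:n
    } else {
      idx_src[[axis]] <- 2:n; idx_dst[[axis]] <- seq_len(n - 1L)
    }
    out <- do.call(`[<-`, c(list(out), idx_dst,
                            list(do.call(`[`, c(list(a), idx_src)))))
    out
  }
  near_fg <- array(FALSE, dim = dims)
  for (ax in 1:3) for (by in c(1L, -1L))
    near_fg <- near_fg | pad_shift(mask, ax, by)
  # only in-grid background exists (as in the package's distance map), so
  # callers must pass masks whose boundary lies inside the grid
  shell <- which(bg & near_fg)
  fg_ind <- arrayInd(fg, dims)
  best <- rep(Inf, nrow(fg_ind))
  if (length(shell) > 0L) {
    sh_ind <- arrayInd(shell, dims)
    chunk <- 2000L
    for (s in seq(1L, nrow(fg_ind), by = chunk)) {
      e <- min(s + chunk - 1L, nrow(fg_ind))
      d2 <- outer(fg_ind[s:e, 1] * spacing[1], sh_ind[, 1] * spacing[1],
                  "-")^2 +
        outer(fg_ind[s:e, 2] * spacing[2], sh_ind[, 2] * spacing[2], "-")^2 +
        outer(fg_ind[s:e, 3] * spacing[3], sh_ind[, 3] * spacing[3], "-")^2
      best[s:e] <- pmin(best[s:e], sqrt(apply(d2, 1, min)))
    }
  }
  list(fg = fg, distance = best)
}

# Interior distances without the virtual outside-the-grid background: the
# package's distance map only sees background voxels present in the grid, so
# tests that compare against it must use this variant on masks that touch no
# grid face, or masks padded so the face never matters. Masks produced by
# random_blob_mask never touch a face.
oracle_subpleural_labels <- function(mask, spacing, depth_mm) {
  o <- oracle_interior_distance(mask, spacing)
  sub <- array(FALSE, dim = dim(mask))
  sub[o$fg[o$distance <= depth_mm]] <- TRUE
  sub
}

# random smooth foreground: union of a few random ellipsoids, kept off the
# grid faces so the mask boundary is entirely inside the grid
random_blob_mask <- function(dims, spacing, n_blobs = 3) {
  ext <- dims * spacing
  cx <- (seq_len(dims[1]) - 0.5) * spacing[1]
  cy <- (seq_len(dims[2]) - 0.5) * spacing[2]
  cz <- (seq_len(dims[3]) - 0.5) * spacing[3]
  mask <- array(FALSE, dim = dims)
  for (b in seq_len(n_blobs)) {
    ctr <- ext * runif(3, 0.3, 0.7)
    ax <- ext * runif(3, 0.08, 0.22)
    tx <- ((cx - ctr[1]) / ax[1])^2
    ty <- ((cy - ctr[2]) / ax[2])^2
    tz <- ((cz - ctr[3]) / ax[3])^2
    mask <- mask | (outer(outer(tx, ty, "+"), tz, "+") <= 1)
  }
  # clear the faces defensively
  mask[c(1, dims[1]), , ] <- FALSE
  mask[, c(1, dims[2]), ] <- FALSE
  mask[, , c(1, dims[3])] <- FALSE
  mask
}

# Triple-loop fat-voxel count over the ground-truth sphere equations,
# independent of both the generator's rasterizer and the quantifier.
# Spheres never overlap (the generator forbids it), so looping each
# sphere's bounding box and summing is exact.
oracle_sphere_voxel_count <- function(dims, spacing, spheres) {
  count <- 0L
  for (s in spheres) {
    rng <- lapply(1:3, function(ax) {
      lo <- max(1L, floor((s$center[ax] - s$radius_mm) / spacing[ax]))
      hi <- min(dims[ax], ceiling((s$center[ax] + s$radius_mm) /
                                    spacing[ax] + 1))
      lo:hi
    })
    for (i in rng[[1]]) for (j in rng[[2]]) for (k in rng[[3]]) {
      p <- (c(i, j, k) - 0.5) * spacing
      if (sum((p - s$center)^2) <= s$radius_mm^2) count <- count + 1L
    }
  }
  count
}

# Hand-rolled Kruskal-Wallis H with tie correction; ranks computed by
# explicit sorting rather than rank().
oracle_kw_H <- function(groups) {
  values <- unlist(groups)
  n <- length(values)
  ord <- order(values)
  rk <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && values[ord[j + 1L]] == values[ord[i]]) j <- j + 1L
    rk[ord[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  fac <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (n * (n + 1)) *
    sum(tapply(rk, fac, sum)^2 / lengths(groups)) - 3 * (n + 1)
  tie <- table(values)
  corr <- 1 - sum(tie^3 - tie) / (n^3 - n)
  if (corr == 0) 0 else H / corr
}

# Hand-rolled Dunn z values on the same explicit ranks.
oracle_dunn_z <- function(groups) {
  values <- unlist(groups)
  n <- length(values)
  ord <- order(values)
  rk <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && values[ord[j + 1L]] == values[ord[i]]) j <- j + 1L
    rk[ord[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  fac <- rep(seq_along(groups), lengths(groups))
  tie <- table(values)
  v <- n * (n + 1) / 12 - sum(tie^3 - tie) / (12 * (n - 1))
  out <- NULL
  for (a in seq_along(groups)) for (b in seq_along(groups)) {
    if (b <= a) next
    se <- sqrt(v * (1 / lengths(groups)[a] + 1 / lengths(groups)[b]))
    z <- (mean(rk[fac == a]) - mean(rk[fac == b])) / se
    out <- rbind(out, data.frame(a = a, b = b, z = z))
  }
  out
}

# small helper: phantom with a single fat sphere at the left lung centre
single_sphere_spec <- function(radius_mm = 10, noise_sd = 0, seed = 1L) {
  phantom_spec(
    fat = list(list(center = c(24, 48, 48), radius_mm = radius_mm,
                    hu = -100)),
    noise_sd = noise_sd, seed = seed)
}
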