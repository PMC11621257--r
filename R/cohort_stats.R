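#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardized sample skewness (D'Agostino's transformation)
#' and kurtosis (Anscombe-Glynn transformation) into
#' `K2 = Z_skew^2 + Z_kurt^2`, referred to a chi-square distribution with
#' 2 degrees of freedom. The transformations are undefined below n = 8; for
#' 8 <= n < 20 the chi-square approximation is weak and a warning is issued.
#'
#' @param x numeric vector, n >= 8.
#' @return List with `statistic` (K2), `p_value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L)
    pf_stop("pulmofat_stats_error",
            "D'Agostino-Pearson test requires n >= 8 (got ", n, ")")
  if (n < 20L)
    warning("D'Agostino-Pearson chi-square approximation is weak for n < 20",
            call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0)
    pf_stop("pulmofat_stats_error", "all values identical: skewness and ",
            "kurtosis are undefined")
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2

  # skewness: D'Agostino (1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    pf_stop("pulmofat_stats_error", "need at least 2 groups")
  sizes <- vapply(groups, length, 0L)
  if (any(sizes == 0L))
    pf_stop("pulmofat_stats_error", "group(s) ",
            paste(which(sizes == 0L), collapse = ", "), " are empty")
  if (any(!vapply(groups, function(g) all(is.finite(g)), TRUE)))
    pf_stop("pulmofat_stats_error", "groups contain non-finite values")
  invisible(sizes)
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based H with tie correction, referred to chi-square with k-1
#' degrees of freedom. The degenerate all-ties case (every observation
#' equal) is defined as H = 0 rather than 0/0.
#'
#' @param groups list of numeric vectors, one per group.
#' @return List with `H`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups)
  k <- length(groups)
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3L)
    pf_stop("pulmofat_stats_error", "need a total of at least 3 observations")
  if (length(unique(values)) == 1L)
    return(list(H = 0, p_value = 1, df = k - 1L))
  fac <- factor(rep(seq_len(k), vapply(groups, length, 0L)))
  kt <- kruskal.test(values, fac)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Dunn's post hoc pairwise comparisons
#'
#' Pairwise z statistics from pooled-rank mean differences with
#' tie-corrected variance, two-sided p-values, and a multiplicity
#' adjustment (Bonferroni-style multiplication by the number of
#' comparisons, capped at 1, by default).
#'
#' @param groups list (optionally named) of numeric vectors.
#' @param adjustment passed to [stats::p.adjust()]; default `"bonferroni"`.
#' @return data.frame with columns `group1`, `group2`, `z`, `p_raw`, `p_adj`.
#' @export
dunn_posthoc <- function(groups, adjustment = "bonferroni") {
  sizes <- check_groups(groups)
  k <- length(groups)
  nms <- names(groups) %||% paste0("group", seq_len(k))
  if (is.null(names(groups))) names(groups) <- nms
  values <- unlist(groups, use.names = FALSE)
  n <- length(values)
  r <- rank(values)                      # average ranks on ties
  fac <- rep(seq_len(k), sizes)
  rbar <- tapply(r, fac, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  # variance of a rank-mean difference under H0, with tie correction
  base_var <- n * (n + 1) / 12 - tie_term / (12 * (n - 1))
  pairs <- utils::combn(k, 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (c_ in seq_len(ncol(pairs))) {
    i <- pairs[1, c_]; j <- pairs[2, c_]
    se <- sqrt(base_var * (1 / sizes[i] + 1 / sizes[j]))
    z[c_] <- if (se == 0) 0 else (rbar[[i]] - rbar[[j]]) / se
    p_raw[c_] <- 2 * pnorm(-abs(z[c_]))
  }
  data.frame(group1 = nms[pairs[1, ]], group2 = nms[pairs[2, ]],
             z = z, p_raw = p_raw,
             p_adj = p.adjust(p_raw, method = adjustment),
             stringsAsFactors = FALSE)
}

#' Median and interquartile descriptives
#'
#' Quartiles by linear interpolation between order statistics
#' ([stats::quantile()] type 7). Both the (q1, q3) range and its width are
#' reported, since cohort tables print both styles.
#'
#' @param x numeric vector, n >= 1.
#' @return List with `median`, `q1`, `q3`, `iqr_width`, `n`.
#' @export
describe_quartiles <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L)
    pf_stop("pulmofat_stats_error", "cannot describe an empty sample")
  if (any(!is.finite(x)))
    pf_stop("pulmofat_stats_error", "sample contains non-finite values")
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2], q1 = q[1], q3 = q[3], iqr_width = q[3] - q[1],
       n = length(x))
}

#' Run the full cohort-comparison battery
#'
#' Per-group normality assessment (D'Agostino-Pearson), Kruskal-Wallis
#' omnibus test, Dunn post hoc pairwise comparisons with multiplicity
#' adjustment, and median/IQR descriptives. The nonparametric path is always
#' run; normality results are reported for transparency, not used to switch
#' methods.
#'
#' @param table data.frame with one row per subject.
#' @param metric name of the metric column to compare (e.g. `"pfi_pct"`).
#' @param group_col name of the group column; default `"group"`.
#' @param alpha significance level; default 0.05.
#' @param adjustment Dunn multiplicity adjustment; default `"bonferroni"`.
#' @return Object of class `cohort_test_report` with `normality`,
#'   `omnibus`, `posthoc` (with a `significant` flag at `alpha`),
#'   `descriptives`, `alpha`, `metric`.
#' @export
run_battery <- function(table, metric, group_col = "group", alpha = 0.05,
                        adjustment = "bonferroni") {
  if (inherits(table, "cohort_sim")) table <- table$table
  if (!is.data.frame(table))
    pf_stop("pulmofat_input_error", "table must be a data.frame")
  for (col in c(metric, group_col))
    if (!col %in% names(table))
      pf_stop("pulmofat_input_error", "column '", col,
              "' is missing from the cohort table")
  vals <- table[[metric]]
  if (any(!is.finite(vals)))
    pf_stop("pulmofat_stats_error", "metric '", metric,
            "' contains non-finite values")
  groups <- split(vals, factor(table[[group_col]]))

  normality <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    if (length(x) >= 8L) {
      dp <- suppressWarnings(dagostino_pearson(x))
      data.frame(group = g, n = length(x), K2 = dp$statistic,
                 p_value = dp$p_value, stringsAsFactors = FALSE)
    } else {
      data.frame(group = g, n = length(x), K2 = NA_real_,
                 p_value = NA_real_, stringsAsFactors = FALSE)
    }
  }))

  omnibus <- kruskal_wallis(groups)
  posthoc <- dunn_posthoc(groups, adjustment = adjustment)
  posthoc$significant <- posthoc$p_adj < alpha

  descriptives <- do.call(rbind, lapply(names(groups), function(g) {
    d <- describe_quartiles(groups[[g]])
    data.frame(group = g, n = d$n, median = d$median, q1 = d$q1, q3 = d$q3,
               iqr_width = d$iqr_width, stringsAsFactors = FALSE)
  }))

  structure(
    list(normality = normality, omnibus = omnibus, posthoc = posthoc,
         descriptives = descriptives, alpha = alpha, metric = metric,
         adjustment = adjustment),
    class = "cohort_test_report"
  )
}

#' @export
print.cohort_test_report <- function(x, ...) {
  cat("Cohort comparison of '", x$metric, "' (alpha = ", x$alpha, ")\n",
      sep = "")
  cat("Descriptives (median [q1-q3]):\n")
  for (i in seq_len(nrow(x$descriptives))) {
    d <- x$descriptives[i, ]
    cat(sprintf("  %-10s n=%3d  %.4g [%.4g-%.4g]\n", d$group, d$n, d$median,
                d$q1, d$q3))
  }
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.3g\n", x$omnibus$H,
              x$omnibus$df, x$omnibus$p_value))
  cat("Dunn post hoc (", x$adjustment, "-adjusted):\n", sep = "")
  for (i in seq_len(nrow(x$posthoc))) {
    p <- x$posthoc[i, ]
    cat(sprintf("  %s vs %s: z = %.4g, p_adj = %.3g%s\n", p$group1, p$group2,
                p$z, p$p_adj, if (p$significant) " *" else ""))
  }
  invisible(x)
}
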