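# Minimal DICOM part-10 reader for uncompressed single-frame CT series.
# Supports the two ubiquitous transfer syntaxes (explicit and implicit VR
# little endian); compressed or big-endian files are rejected with a format
# error. Only the tags needed for HU volumetrics are extracted.

u16 <- function(raw, pos) {
  readBin(raw[pos:(pos + 1L)], "integer", size = 2L, endian = "little",
          signed = FALSE)
}
u32 <- function(raw, pos) {
  lo <- u16(raw, pos); hi <- u16(raw, pos + 2L)
  hi * 65536 + lo
}

# VRs with a 2-byte reserved field and 4-byte length in explicit encoding
long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    pf_stop("pulmofat_io_error", "'", path, "' is not a DICOM part-10 file")
  tags <- list()
  pos <- 133L

  read_element <- function(pos, explicit) {
    group <- u16(raw, pos); elem <- u16(raw, pos + 2L)
    if (explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(raw, pos + 8L); hdr <- 12L
      } else {
        len <- u16(raw, pos + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_; len <- u32(raw, pos + 4L); hdr <- 8L
    }
    if (len >= 4294967295)
      pf_stop("pulmofat_io_error", "'", path,
              "': undefined-length element (", sprintf("%04X,%04X", group, elem),
              ") is not supported")
    list(group = group, elem = elem, vr = vr, len = len,
         value_at = pos + hdr, next_at = pos + hdr + as.integer(len))
  }

  # file meta information (group 0002) is always explicit VR little endian
  ts <- NULL
  while (pos + 7L <= length(raw)) {
    el <- read_element(pos, explicit = TRUE)
    if (el$group != 2L) break
    if (el$elem == 0x0010 && el$len > 0L) {
      v <- raw[el$value_at:(el$value_at + el$len - 1L)]
      ts <- sub("\\s+$", "", rawToChar(v[v != as.raw(0L)]))
    }
    pos <- el$next_at
  }
  if (is.null(ts))
    pf_stop("pulmofat_io_error", "'", path, "': missing transfer syntax UID")
  explicit <- ts == "1.2.840.10008.1.2.1"
  if (!explicit && ts != "1.2.840.10008.1.2")
    pf_stop("pulmofat_io_error", "'", path, "': unsupported transfer syntax '",
            ts, "' (only uncompressed little endian is supported)")

  want <- c("0008,0018", "0018,0050", "0020,000E", "0020,0032", "0020,0037",
            "0028,0010", "0028,0011", "0028,0030", "0028,0100", "0028,0103",
            "0028,1052", "0028,1053", "7FE0,0010")
  while (pos + 7L <= length(raw)) {
    el <- read_element(pos, explicit)
    key <- sprintf("%04X,%04X", el$group, el$elem)
    if (key %in% want && el$len > 0L)
      tags[[key]] <- raw[el$value_at:(el$value_at + el$len - 1L)]
    pos <- el$next_at
  }
  tags
}

tag_str <- function(tags, key) {
  v <- tags[[key]]
  if (is.null(v)) return(NULL)
  sub("\\s+$", "", rawToChar(v[v != as.raw(0L)]))
}
tag_num <- function(tags, key) {
  s <- tag_str(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
tag_u16 <- function(tags, key) {
  v <- tags[[key]]
  if (is.null(v)) return(NULL)
  u16(v, 1L)
}

load_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    pf_stop("pulmofat_io_error", "no files in DICOM directory '", dir, "'")
  slices <- lapply(files, parse_dicom_file)

  uids <- vapply(slices, function(t) tag_str(t, "0020,000E") %||% "", "")
  if (length(unique(uids)) > 1L)
    pf_stop("pulmofat_io_error", "directory '", dir, "' mixes ",
            length(unique(uids)), " DICOM series; expected one")

  first <- slices[[1]]
  iop <- tag_num(first, "0020,0037") %||% c(1, 0, 0, 0, 1, 0)
  rowdir <- iop[1:3]; coldir <- iop[4:6]
  normal <- c(rowdir[2] * coldir[3] - rowdir[3] * coldir[2],
              rowdir[3] * coldir[1] - rowdir[1] * coldir[3],
              rowdir[1] * coldir[2] - rowdir[2] * coldir[1])

  one_slice <- function(tags, path) {
    rows <- tag_u16(tags, "0028,0010"); cols <- tag_u16(tags, "0028,0011")
    bits <- tag_u16(tags, "0028,0100") %||% 16L
    signed <- (tag_u16(tags, "0028,0103") %||% 0L) == 1L
    slope <- tag_num(tags, "0028,1053"); icpt <- tag_num(tags, "0028,1052")
    if (is.null(slope) || is.null(icpt))
      pf_stop("pulmofat_io_error", "'", path, "': missing rescale slope/",
              "intercept tags; refusing to assume identity rescale")
    if (is.null(rows) || is.null(cols) || bits != 16L)
      pf_stop("pulmofat_io_error", "'", path,
              "': unsupported pixel format (need 16-bit single frame)")
    px <- tags[["7FE0,0010"]]
    if (is.null(px) || length(px) < 2L * rows * cols)
      pf_stop("pulmofat_io_error", "'", path, "': missing or short pixel data")
    v <- readBin(px, "integer", n = rows * cols, size = 2L,
                 endian = "little", signed = signed)
    ipp <- tag_num(tags, "0020,0032") %||% c(0, 0, 0)
    # row-major storage: columns vary fastest, so this matrix is [col, row]
    list(pix = matrix(slope * v + icpt, nrow = cols, ncol = rows),
         pos = sum(ipp * normal), ipp = ipp,
         ps = tag_num(tags, "0028,0030") %||% c(1, 1),
         thick = tag_num(tags, "0018,0050") %||% 1)
  }
  parsed <- Map(one_slice, slices, files)

  ord <- order(vapply(parsed, `[[`, 0, "pos"))
  parsed <- parsed[ord]
  nz <- length(parsed)
  dz <- if (nz >= 2L) {
    gaps <- diff(vapply(parsed, `[[`, 0, "pos"))
    if (any(gaps <= 0))
      pf_stop("pulmofat_io_error", "duplicate slice positions in '", dir, "'")
    if ((max(gaps) - min(gaps)) / mean(gaps) > 0.01)
      pf_stop("pulmofat_io_error", "non-uniform slice spacing in '", dir,
              "' (gaps ", signif(min(gaps), 5), "-", signif(max(gaps), 5),
              " mm exceed 1% tolerance); volume would be ill-defined")
    mean(gaps)
  } else parsed[[1]]$thick

  ps <- parsed[[1]]$ps               # (row spacing = y, column spacing = x)
  dims <- c(nrow(parsed[[1]]$pix), ncol(parsed[[1]]$pix), nz)
  data <- array(0, dim = dims)
  for (k in seq_len(nz)) data[, , k] <- parsed[[k]]$pix

  # affine in RAS (DICOM is LPS: negate x and y rows)
  lps <- cbind(rowdir * ps[2], coldir * ps[1], normal * dz, parsed[[1]]$ipp)
  ras <- lps * c(-1, -1, 1)
  aff <- rbind(ras, c(0, 0, 0, 1))

  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- c(ps[2], ps[1], dz)
  RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
  src <- RNifti::orientation(img)
  RNifti::orientation(img) <- canonical_orientation
  aff2 <- RNifti::xform(img)
  ct_volume(array(as.numeric(img), dim = dim(img)),
            spacing = as.numeric(RNifti::pixdim(img))[1:3],
            origin = as.numeric(aff2[1:3, 4]),
            orientation = canonical_orientation, source_orientation = src)
}
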