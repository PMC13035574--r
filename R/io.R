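# ENVI cube and PNG mask I/O.
#
# Cubes are stored as an ENVI text header (.hdr) next to a flat binary file.
# BSQ, BIL and BIP interleaves are all accepted on read; BSQ is written.
# Wavelength metadata is mandatory: a cube without its wavelength axis is
# not interpretable by any downstream stage, so readers reject rather than
# coerce.

.envi_dtypes <- list(
  `1` = list(what = "integer", size = 1L, signed = FALSE),
  `2` = list(what = "integer", size = 2L, signed = TRUE),
  `3` = list(what = "integer", size = 4L, signed = TRUE),
  `4` = list(what = "numeric", size = 4L, signed = TRUE),
  `5` = list(what = "numeric", size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

#' Write a hyperspectral cube as ENVI header + binary
#'
#' Writes `<path>` (band-sequential binary, little-endian float64) and
#' `<path>.hdr` (ENVI text header carrying dimensions, interleave,
#' wavelengths and the patient id).
#'
#' @param cube A [hypercube()].
#' @param path Data-file path; the header gets a `.hdr` suffix.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$reflectance)
  hdr <- c(
    "ENVI",
    "file type = ENVI Standard",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("patient id = %s", cube$patient_id),
    sprintf("wavelength = { %s }",
            paste(format(cube$wavelengths, digits = 17, trim = TRUE,
                         scientific = FALSE), collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  # BSQ: band-major, rows within band scanned line by line
  v <- as.vector(aperm(cube$reflectance, c(2, 1, 3)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(v, con, size = 8L, endian = "little")
  invisible(path)
}

# Parse an ENVI header into a named list (values of {...} fields are
# numeric vectors).
.read_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  txt <- sub("^ENVI[ \t]*\n", "", txt)
  out <- list()
  # brace-delimited fields may span lines
  pat <- "([a-zA-Z ][a-zA-Z0-9 ]*?)[ \t]*=[ \t]*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  starts <- as.vector(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    if (starts[i] < 0) next
    field <- substr(txt, starts[i], starts[i] + lens[i] - 1)
    key <- tolower(trimws(sub("=.*", "", field)))
    val <- trimws(sub("^[^=]*=", "", field))
    if (startsWith(val, "{")) {
      inner <- gsub("[{}]", "", val)
      parts <- trimws(strsplit(inner, ",")[[1]])
      num <- suppressWarnings(as.numeric(parts))
      out[[key]] <- if (anyNA(num)) parts else num
    } else out[[key]] <- val
  }
  out
}

#' Read a hyperspectral cube from an ENVI file pair
#'
#' Accepts BSQ, BIL and BIP interleaves and ENVI data types 1, 2, 3, 4, 5
#' and 12. The header must declare dimensions consistent with the binary
#' payload and a wavelength list matching the band count.
#'
#' @param path Data-file path (header expected at `<path>.hdr`, or `path`
#'   with its extension replaced by `.hdr`).
#' @return A [hypercube()].
#' @export
read_cube <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path))
    hdr_path <- sub("\\.[^.]+$", ".hdr", path)
  if (!file.exists(hdr_path))
    stop("format error: ENVI header not found for ", path)
  h <- .read_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  if (!all(need %in% names(h)))
    stop("format error: ENVI header missing required fields")
  w <- as.integer(h[["samples"]]); ht <- as.integer(h[["lines"]])
  b <- as.integer(h[["bands"]])
  if (is.null(h[["wavelength"]]))
    stop("format error: ENVI header has no wavelength metadata")
  wl <- as.numeric(h[["wavelength"]])
  if (length(wl) != b)
    stop("format error: wavelength count (", length(wl),
         ") does not match band count (", b, ")")
  dt <- .envi_dtypes[[as.character(as.integer(h[["data type"]]))]]
  if (is.null(dt))
    stop("format error: unsupported ENVI data type ", h[["data type"]])
  endian <- if (!is.null(h[["byte order"]]) &&
                as.integer(h[["byte order"]]) == 1) "big" else "little"
  offset <- if (!is.null(h[["header offset"]]))
    as.integer(h[["header offset"]]) else 0L
  n <- w * ht * b
  expected <- offset + n * dt$size
  if (file.info(path)$size < expected)
    stop("format error: binary payload smaller than header-declared size")
  con <- file(path, "rb")
  on.exit(close(con))
  if (offset > 0) readBin(con, "raw", offset)
  v <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
               endian = endian)
  interleave <- tolower(h[["interleave"]])
  arr <- switch(interleave,
    bsq = aperm(array(v, c(w, ht, b)), c(2, 1, 3)),
    bil = aperm(array(v, c(w, b, ht)), c(3, 1, 2)),
    bip = aperm(array(v, c(b, w, ht)), c(3, 2, 1)),
    stop("format error: unknown interleave '", interleave, "'"))
  pid <- if (!is.null(h[["patient id"]])) h[["patient id"]] else ""
  hypercube(arr, wl, pid)
}

#' Write / read an annotation mask as an indexed PNG
#'
#' Masks are stored as 8-bit grayscale PNGs with pixel values equal to the
#' label codes (0 unlabeled, 1 esophagus, 2 stomach, 3 cancer).
#'
#' @param mask Integer label matrix.
#' @param path PNG file path.
#' @return `path` invisibly (write); integer matrix (read).
#' @export
write_mask <- function(mask, path) {
  mask <- validate_mask(mask)
  png::writePNG(mask / 255, target = path)
  invisible(path)
}

#' @rdname write_mask
#' @param cube Optional [hypercube()] the mask must align with.
#' @export
read_mask <- function(path, cube = NULL) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  mask <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  validate_mask(mask, cube)
  mask
}

#' Reconstruct an RGB preview from a cube
#'
#' Each channel is the band mean over a wavelength window, min-max scaled
#' to 0..255 over the image. Window defaults sit in hemoglobin-insensitive
#' regions chosen for visual contrast; the preview is cosmetic only.
#'
#' @param cube A [hypercube()].
#' @param windows Named list with `r`, `g`, `b` wavelength windows
#'   (`c(lo, hi)` in nm).
#' @return Integer `H x W x 3` array with values in 0..255.
#' @export
cube_to_rgb <- function(cube,
                        windows = list(r = c(614, 624), g = c(540, 550),
                                       b = c(530, 540))) {
  stopifnot(inherits(cube, "hypercube"))
  chans <- lapply(windows, function(wd) {
    sel <- cube$wavelengths >= wd[1] & cube$wavelengths <= wd[2]
    if (!any(sel))
      stop("range error: RGB window [", wd[1], ", ", wd[2],
           "] outside the wavelength range")
    m <- apply(cube$reflectance[, , sel, drop = FALSE], c(1, 2), mean)
    rng <- range(m)
    if (rng[2] > rng[1]) round(255 * (m - rng[1]) / (rng[2] - rng[1]))
    else matrix(0, nrow(m), ncol(m))
  })
  out <- array(0L, c(dim(cube$reflectance)[1:2], 3L))
  out[, , 1] <- as.integer(chans$r)
  out[, , 2] <- as.integer(chans$g)
  out[, , 3] <- as.integer(chans$b)
  out
}

#' Write a phantom cohort to disk
#'
#' Writes each patient's cube (ENVI), mask (PNG) and a cohort manifest CSV
#' with columns `patient_id`, `cube`, `mask`, `stage`.
#'
#' @param cohort A `phantom_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(p) {
    cube_file <- paste0(p$patient_id, ".raw")
    mask_file <- paste0(p$patient_id, "_mask.png")
    write_cube(p$cube, file.path(dir, cube_file))
    write_mask(p$mask, file.path(dir, mask_file))
    data.frame(patient_id = p$patient_id, cube = cube_file,
               mask = mask_file, stage = p$stage,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv`.
#' @return A `phantom_cohort` (without the generating parameters).
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  patients <- lapply(seq_len(nrow(manifest)), function(i) {
    cube <- read_cube(file.path(dir, manifest$cube[i]))
    mask <- read_mask(file.path(dir, manifest$mask[i]), cube)
    list(patient_id = manifest$patient_id[i], cube = cube, mask = mask,
         params = NULL, stage = manifest$stage[i])
  })
  structure(patients, class = "phantom_cohort")
}
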