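## Volume I/O: multi-page grayscale TIFF with a JSON pitch sidecar.
## Reading goes through tiff::readTIFF (which handles 8/16-bit integer and
## 32-bit float input); writing uses a minimal baseline-TIFF float32 writer,
## because no installed writer stores IEEE float samples outside [0, 1]
## faithfully.

sidecar_path <- function(path) paste0(path, ".json")

# Minimal little-endian baseline TIFF writer: one grayscale float32 strip per
# page, uncompressed.
write_float_tiff <- function(pages, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w <- ncol(pages[[1]])   # image width  = number of columns (x)
  h <- nrow(pages[[1]])   # image length = number of rows (y)
  n <- length(pages)
  bytes_per_page <- w * h * 4L
  data_start <- 8L
  ifd_start <- data_start + n * bytes_per_page
  ifd_size <- 2L + 12L * 10L + 4L
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_start, con, size = 4, endian = "little")
  for (p in pages)  # row-major pixel order: rows are y, columns are x
    writeBin(as.numeric(t(p)), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT: left-justified in the 4-byte value field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (k in seq_len(n)) {
    writeBin(10L, con, size = 2, endian = "little")
    entry(256, 4, 1, w)                               # ImageWidth
    entry(257, 4, 1, h)                               # ImageLength
    entry(258, 3, 1, 32)                              # BitsPerSample
    entry(259, 3, 1, 1)                               # Compression: none
    entry(262, 3, 1, 1)                               # Photometric: min-is-black
    entry(273, 4, 1, data_start + (k - 1L) * bytes_per_page)  # StripOffsets
    entry(277, 3, 1, 1)                               # SamplesPerPixel
    entry(278, 4, 1, h)                               # RowsPerStrip
    entry(279, 4, 1, bytes_per_page)                  # StripByteCounts
    entry(339, 3, 1, 3)                               # SampleFormat: IEEE float
    nxt <- if (k < n) ifd_start + k * ifd_size else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Write a volume as a multi-page 32-bit float TIFF
#'
#' One grayscale page per z slice, IEEE float32 samples, with the voxel pitch
#' (and any extra metadata) in a JSON sidecar `<path>.json`. Round trips
#' losslessly at float32 precision through [read_volume()].
#'
#' @param vol An [ri_volume()].
#' @param path Output TIFF path.
#' @param metadata Optional named list merged into the sidecar.
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path, metadata = list()) {
  stopifnot(inherits(vol, "ri_volume"))
  d <- dim(vol$data)
  pages <- lapply(seq_len(d[3]), function(k) t(vol$data[, , k]))  # [y, x]
  write_float_tiff(pages, path)
  side <- c(list(pitch_um = as.numeric(vol$pitch),
                 shape = as.integer(d), format = "float32"), metadata)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a volume from a multi-page TIFF
#'
#' Accepts 8/16-bit integer (promoted to float, with the integer full-scale
#' recorded in attribute `scale`) and 32-bit float grayscale stacks. The
#' voxel pitch is taken from the `pitch` argument or the JSON sidecar written
#' by [write_volume()].
#'
#' @param path TIFF path.
#' @param pitch Voxel pitch in um (length 1 or 3); overrides the sidecar.
#' @return An [ri_volume()].
#' @export
read_volume <- function(path, pitch = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(
    suppressWarnings(tiff::readTIFF(path, all = TRUE, as.is = TRUE)),
    error = function(e)
      tryCatch(tiff::readTIFF(path, all = TRUE),
               error = function(e2)
                 stop("cannot read TIFF '", path, "': ", conditionMessage(e2),
                      call. = FALSE)))
  if (!is.list(pages)) pages <- list(pages)
  scale <- 1
  if (is.integer(pages[[1]])) {
    info <- attributes(tiff::readTIFF(path, info = TRUE, as.is = TRUE))
    bits <- if (!is.null(info$bits.per.sample)) info$bits.per.sample else 16L
    scale <- 2^bits - 1
  }
  if (length(dim(pages[[1]])) == 3L)  # single page stored with z as channels
    pages <- lapply(seq_len(dim(pages[[1]])[3]),
                    function(k) pages[[1]][, , k])
  d <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  a <- array(0, d)
  for (k in seq_len(d[3])) a[, , k] <- t(pages[[k]])
  if (is.null(pitch)) {
    sp <- sidecar_path(path)
    if (file.exists(sp)) {
      pitch <- jsonlite::read_json(sp, simplifyVector = TRUE)$pitch_um
    } else {
      stop("voxel pitch for '", path, "' is unknown: pass pitch= or provide ",
           "a JSON sidecar '", sp, "' with a pitch_um entry")
    }
  }
  out <- ri_volume(a, pitch)
  attr(out, "scale") <- scale
  out
}

#' Write / read a cell mask as an 8-bit TIFF stack
#'
#' @param mask A [cell_mask()].
#' @param path TIFF path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "cell_mask"))
  d <- dim(mask$mask)
  pages <- lapply(seq_len(d[3]), function(k) t(mask$mask[, , k]) * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  m <- array(FALSE, d)
  for (k in seq_len(d[3])) m[, , k] <- t(pages[[k]]) > 0.5
  cell_mask(m, "external")
}
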