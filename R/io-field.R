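## Columnar text I/O for displacement and traction fields. The text files
## carry 9 significant digits; an optional binary sidecar preserves full
## precision and is used preferentially on read.

#' Write a displacement or traction field to columnar text
#'
#' Displacement fields: columns `x y z ux uy uz valid quality` (positions and
#' vectors in micrometres). Traction fields: `x y Tx Ty Tz` (positions um,
#' tractions Pa). Values are written with 9 significant digits; with
#' `binary = TRUE` an RDS sidecar `<path>.rds` additionally preserves full
#' precision and takes precedence when reading.
#'
#' @param field A `displacement_field` or `traction_field`.
#' @param path Output text path.
#' @param binary Also write the full-precision sidecar.
#' @return The path, invisibly.
#' @export
write_field <- function(field, path, binary = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) sprintf("%.9g", x)
  if (inherits(field, "displacement_field")) {
    co <- expand.grid(i = seq_along(field$x), j = seq_along(field$y),
                      k = seq_along(field$z))
    writeLines(c("# ritfm field v1",
                 "# type: displacement",
                 "# units: um",
                 sprintf("# grid: %d %d %d", length(field$x),
                         length(field$y), length(field$z)),
                 "x y z ux uy uz valid quality"), con)
    df <- data.frame(
      x = fmt(field$x[co$i]), y = fmt(field$y[co$j]), z = fmt(field$z[co$k]),
      ux = fmt(field$u[cbind(co$i, co$j, co$k, 1)]),
      uy = fmt(field$u[cbind(co$i, co$j, co$k, 2)]),
      uz = fmt(field$u[cbind(co$i, co$j, co$k, 3)]),
      valid = as.integer(field$valid[cbind(co$i, co$j, co$k)]),
      quality = fmt(field$quality[cbind(co$i, co$j, co$k)]))
  } else if (inherits(field, "traction_field")) {
    co <- expand.grid(i = seq_along(field$x), j = seq_along(field$y))
    writeLines(c("# ritfm field v1",
                 "# type: traction",
                 "# units: Pa",
                 sprintf("# grid: %d %d", length(field$x), length(field$y)),
                 "x y Tx Ty Tz"), con)
    df <- data.frame(
      x = fmt(field$x[co$i]), y = fmt(field$y[co$j]),
      Tx = fmt(field$tx[cbind(co$i, co$j)]),
      Ty = fmt(field$ty[cbind(co$i, co$j)]),
      Tz = fmt(field$tz[cbind(co$i, co$j)]))
  } else stop("unsupported field class")
  write.table(df, con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (binary) saveRDS(field, paste0(path, ".rds"))
  invisible(path)
}

#' Read a field written by [write_field()]
#'
#' @param path Text path.
#' @return A `displacement_field` or `traction_field`, depending on the file's
#'   type header. A missing validity column defaults to all-valid with a
#'   warning; non-finite vectors not flagged invalid are rejected.
#' @export
read_field <- function(path) {
  rds <- paste0(path, ".rds")
  if (file.exists(rds)) return(readRDS(rds))
  lines <- readLines(path, n = 10L)
  hdr <- grep("^#", lines, value = TRUE)
  type <- sub(".*type:\\s*", "", grep("type:", hdr, value = TRUE)[1])
  units <- sub(".*units:\\s*", "", grep("units:", hdr, value = TRUE)[1])
  gridln <- sub(".*grid:\\s*", "", grep("grid:", hdr, value = TRUE)[1])
  if (is.na(type)) stop("not a ritfm field file (no type header): ", path)
  gd <- as.integer(strsplit(trimws(gridln), "\\s+")[[1]])
  colline <- lines[!grepl("^#", lines)][1]
  cols <- strsplit(trimws(colline), "\\s+")[[1]]
  df <- read.table(path, skip = which(!grepl("^#", lines))[1],
                   col.names = cols)
  if (type == "displacement") {
    if (!identical(units, "um"))
      stop("unit mismatch: displacement fields must be in um, found '",
           units, "'")
    if (!"valid" %in% cols) {
      warning("no validity column; assuming all nodes valid")
      df$valid <- 1L
    }
    if (!"quality" %in% cols) df$quality <- NA_real_
    x <- sort(unique(df$x)); y <- sort(unique(df$y)); z <- sort(unique(df$z))
    dims <- c(length(x), length(y), length(z))
    if (!identical(dims, gd)) stop("grid header does not match data")
    i <- match(df$x, x); j <- match(df$y, y); k <- match(df$z, z)
    u <- array(NA_real_, c(dims, 3))
    u[cbind(i, j, k, 1)] <- df$ux
    u[cbind(i, j, k, 2)] <- df$uy
    u[cbind(i, j, k, 3)] <- df$uz
    valid <- array(FALSE, dims); valid[cbind(i, j, k)] <- df$valid > 0
    qual <- array(NA_real_, dims); qual[cbind(i, j, k)] <- df$quality
    bad_nan <- valid & (!is.finite(u[, , , 1]) | !is.finite(u[, , , 2]) |
                        !is.finite(u[, , , 3]))
    if (any(bad_nan))
      stop("non-finite displacement vectors not flagged invalid")
    new_displacement_field(x, y, z, u, valid, qual)
  } else if (type == "traction") {
    if (!identical(units, "Pa"))
      stop("unit mismatch: traction fields must be in Pa, found '", units, "'")
    x <- sort(unique(df$x)); y <- sort(unique(df$y))
    dims <- c(length(x), length(y))
    if (!identical(dims, gd)) stop("grid header does not match data")
    i <- match(df$x, x); j <- match(df$y, y)
    tx <- ty <- tz <- matrix(NA_real_, dims[1], dims[2])
    tx[cbind(i, j)] <- df$Tx; ty[cbind(i, j)] <- df$Ty; tz[cbind(i, j)] <- df$Tz
    if (any(!is.finite(tx)) || any(!is.finite(ty)) || any(!is.finite(tz)))
      stop("non-finite traction values")
    new_traction_field(tx, ty, tz,
                       list(x = x, y = y,
                            pitch = c(if (dims[1] > 1) diff(x)[1] else 1,
                                      if (dims[2] > 1) diff(y)[1] else 1)))
  } else stop("unknown field type: ", type)
}
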