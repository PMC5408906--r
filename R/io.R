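#' Read a reflectivity curve from a plain-text column file
#'
#' Parses the de-facto reflectometry exchange format: whitespace- or
#' comma-delimited columns `Q  R  [dR  [dQ]]`, with `#`-prefixed comment or
#' header lines skipped. Q must be strictly increasing and positive. If the
#' file carries no dR column, uncertainties are synthesised as
#' `dr_floor * R` with a warning, so downstream chi-squared weighting remains
#' defined.
#'
#' @param path file path.
#' @param dr_floor relative uncertainty used when no dR column is present.
#' @return A [refl_curve()] tibble.
#' @export
read_reflectivity <- function(path, dr_floor = 0.02) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) abort(paste0(path, ": no data lines"))
  rows <- lapply(keep, function(i) {
    fields <- strsplit(trimws(gsub(",", " ", lines[[i]])), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2 || anyNA(vals)) {
      abort(sprintf("%s: parse error at line %d ('%s')", path, i, lines[[i]]))
    }
    vals
  })
  ncol <- min(vapply(rows, length, 1L))
  m <- do.call(rbind, lapply(rows, function(v) v[seq_len(ncol)]))
  q <- m[, 1]
  if (any(diff(q) <= 0)) {
    bad <- keep[which(diff(q) <= 0)[1] + 1L]
    abort(sprintf("%s: Q not strictly increasing at line %d", path, bad))
  }
  dr <- if (ncol >= 3) m[, 3] else NULL
  dq <- if (ncol >= 4) m[, 4] else NULL
  if (is.null(dr)) {
    warn(paste0(path, ": no dR column; synthesising dR = ", dr_floor, " * R"))
    dr <- dr_floor * pmax(m[, 2], .Machine$double.xmin)
  }
  refl_curve(q, m[, 2], dr = dr, dq = dq)
}

#' Write a reflectivity curve to a plain-text column file
#'
#' Columns `Q R [dR [dQ]]`, space-delimited, with a short `#` header. The
#' round trip through [read_reflectivity()] preserves values to full double
#' precision.
#'
#' @param curve a [refl_curve()] (or data frame with `q`, `r` and optionally
#'   `dr`, `dq`).
#' @param path output path.
#' @param overwrite overwrite an existing file? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_reflectivity <- function(curve, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    abort(paste0(path, " exists; pass overwrite = TRUE to replace it"))
  }
  cols <- c("q", "r", intersect(c("dr", "dq"), names(curve)))
  m <- as.matrix(as.data.frame(curve)[cols])
  hdr <- paste0("# ", paste(toupper(cols), collapse = " "))
  body <- apply(m, 1, function(row) paste(sprintf("%.12e", row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
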