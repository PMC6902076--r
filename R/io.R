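## Plain-text readers/writers for the cohort on-disk layout:
##   <subject>_timeseries.tsv   header = ROI ids, one row per time point
##   <subject>_motion.txt       whitespace, 6 columns, no header
##   manifest.tsv               subject_id, group, age, sex
##   ground_truth.json          per-subject state labels + design echo

#' Write / read an ROI time-series TSV
#'
#' Files carry a header row of ROI ids and one row per time point. Values
#' are written with 17 significant digits so a round trip reproduces the
#' doubles exactly.
#'
#' @param ts numeric T x R matrix (rows = time points, columns = ROIs).
#' @param path output path.
#' @param roiIds column names; defaults to existing colnames or roi_1..R.
#' @return `writeTimeseries` returns `path` invisibly; `readTimeseries`
#'   returns the numeric matrix with ROI ids as column names.
#' @export
writeTimeseries <- function(ts, path, roiIds = NULL) {
  ts <- as.matrix(ts)
  if (is.null(roiIds)) roiIds <- colnames(ts)
  if (is.null(roiIds)) roiIds <- paste0("roi_", seq_len(ncol(ts)))
  out <- apply(ts, 2, function(col) sprintf("%.17g", col))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(ts))
  colnames(out) <- roiIds
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTimeseries
#' @export
readTimeseries <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (any(is.na(m))) stop("non-numeric values in time-series file: ", path)
  m
}

#' Write / read a 6-column rigid-body motion trace
#'
#' Whitespace-delimited, no header: tx ty tz (mm), rx ry rz (degrees), one
#' row per volume — the common realignment-parameter text dialect.
#'
#' @param motion numeric T x 6 matrix.
#' @param path file path.
#' @return `readMotion` returns the T x 6 numeric matrix.
#' @export
writeMotion <- function(motion, path) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion trace must have 6 columns")
  write.table(format(motion, digits = 10, scientific = FALSE, trim = TRUE),
              path, sep = "  ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeMotion
#' @export
readMotion <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != 6L) stop("motion file must have 6 columns: ", path)
  storage.mode(m) <- "double"
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' Write / read a cohort manifest
#'
#' TSV with columns subject_id, group, age, sex.
#' @param manifest data.frame with those columns.
#' @param path file path.
#' @export
writeManifest <- function(manifest, path) {
  required <- c("subject_id", "group", "age", "sex")
  missing <- setdiff(required, names(manifest))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  write.table(manifest[, required], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "age", "sex")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  df
}

#' Write / read a windowed connectivity tensor
#'
#' One TSV with W rows x E columns of Fisher-z values plus a JSON sidecar
#' (`<path>.json`) recording the window length, step, start indices and a
#' hash of the canonical edge order, so a reader can verify compatibility.
#'
#' @param wfc a [WindowedFC-class].
#' @param path path of the values TSV; the sidecar is written next to it.
#' @return `readWindowedFC` returns the reconstructed [WindowedFC-class].
#' @export
writeWindowedFC <- function(wfc, path) {
  stopifnot(is(wfc, "WindowedFC"))
  vals <- windowValues(wfc)
  out <- apply(vals, 2, function(col) sprintf("%.17g", col))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(vals))
  colnames(out) <- paste0("e", seq_len(ncol(vals)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  E <- ncol(vals)
  N <- as.integer(round((1 + sqrt(1 + 8 * E)) / 2))
  sidecar <- list(
    subject_id = wfc@subjectId,
    window = wfc@window, step = wfc@step, starts = wfc@starts,
    n_roi = N,
    edge_order_hash = sum(as.numeric(edgeIndex(N)) * seq_len(2L * E)) %% 2147483647
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeWindowedFC
#' @export
readWindowedFC <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(read.delim(path, header = TRUE, sep = "\t"))
  storage.mode(vals) <- "double"
  dimnames(vals) <- NULL
  E <- ncol(vals)
  N <- as.integer(round((1 + sqrt(1 + 8 * E)) / 2))
  expected <- sum(as.numeric(edgeIndex(N)) * seq_len(2L * E)) %% 2147483647
  if (!identical(as.numeric(sidecar$edge_order_hash), as.numeric(expected)))
    stop("edge-order hash mismatch in sidecar of ", path)
  new("WindowedFC", subjectId = sidecar$subject_id, values = vals,
      window = as.integer(sidecar$window), step = as.integer(sidecar$step),
      starts = as.integer(sidecar$starts))
}

#' Write / read a square connectivity-variability matrix
#'
#' Square TSV with ROI ids as the header row.
#'
#' @param m symmetric matrix with ROI dimnames (or supply `roiIds`).
#' @param path file path.
#' @param roiIds optional ROI ids used when `m` has no dimnames.
#' @return `readFCVMatrix` returns the symmetric numeric matrix.
#' @export
writeFCVMatrix <- function(m, path, roiIds = NULL) {
  if (is.null(roiIds)) roiIds <- colnames(m)
  if (is.null(roiIds)) roiIds <- paste0("roi_", seq_len(ncol(m)))
  out <- apply(m, 2, function(col) sprintf("%.17g", col))
  colnames(out) <- roiIds
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFCVMatrix
#' @export
readFCVMatrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  rownames(m) <- colnames(m)
  if (nrow(m) != ncol(m)) stop("matrix in ", path, " is not square")
  m
}
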