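#' Read and write distance-trace CSV files
#'
#' Traces are stored as two-column CSV with the exact header
#' `t_s,distance_px`, one row per frame. The round trip is lossless to
#' well below 1e-12 relative error.
#'
#' @param trace A [distance_trace()].
#' @param path File path.
#' @return `write_trace_csv()` returns `path` invisibly;
#'   `read_trace_csv()` returns a [distance_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "distance_trace"))
  df <- data.frame(t_s = format(trace$t_s, digits = 17, trim = TRUE,
                                scientific = FALSE),
                   distance_px = format(trace$d_px, digits = 17,
                                        trim = TRUE, scientific = FALSE))
  names(df) <- c("t_s", "distance_px")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param frame_rate_hz Optional expected frame rate; inferred from the
#'   timestamps when `NULL`.
#' @export
read_trace_csv <- function(path, frame_rate_hz = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), c("t_s", "distance_px")))
    stop("bad header in ", path, ": expected 't_s,distance_px', got '",
         paste(names(raw), collapse = ","), "'")
  t <- suppressWarnings(as.numeric(raw$t_s))
  d <- suppressWarnings(as.numeric(raw$distance_px))
  bad <- which(!is.finite(t) | !is.finite(d))
  if (length(bad))
    stop("malformed rows in ", path, " at line(s) ",
         paste(head(bad + 1L, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  if (is.null(frame_rate_hz)) {
    if (length(t) < 2L) stop("cannot infer frame rate from a 1-row trace")
    frame_rate_hz <- 1 / median(diff(t))
  }
  distance_trace(d, frame_rate_hz, t_s = t)
}

#' Read and write multi-page grayscale TIFF frame stacks
#'
#' Stacks are stored as multi-page grayscale TIFF (8- or 16-bit);
#' intensities are scaled to `[0, 1]` in memory, so a round trip is exact
#' up to quantization (1/255 or 1/65535). When the stack carries ground
#' truth, a plain-text sidecar CSV `frame,eye_x,eye_y,tip_x,tip_y` is
#' written next to the TIFF (suffix `_truth.csv`) and picked up again on
#' read.
#'
#' @param stack A `frame_stack` (see [render_frames()]).
#' @param path TIFF file path.
#' @param bits Bits per sample: 8 or 16.
#' @param truth_path Sidecar CSV path; defaults to `path` with a
#'   `_truth.csv` suffix. Set `NA` to suppress the sidecar.
#' @return `write_tiff_stack()` returns `path` invisibly;
#'   `read_tiff_stack()` returns a `frame_stack`.
#' @export
write_tiff_stack <- function(stack, path, bits = 8, truth_path = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!bits %in% c(8, 16)) stop("'bits' must be 8 or 16")
  n <- dim(stack$pixels)[3]
  pages <- lapply(seq_len(n), function(i) stack$pixels[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  if (is.null(truth_path)) truth_path <- default_truth_path(path)
  if (!is.null(stack$truth) && !is.na(truth_path))
    write.csv(stack$truth, truth_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

default_truth_path <- function(path)
  paste0(tools::file_path_sans_ext(path), "_truth.csv")

#' @rdname write_tiff_stack
#' @param px_scale Pixels per trace distance unit recorded in the
#'   returned stack.
#' @export
read_tiff_stack <- function(path, truth_path = NULL, px_scale = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1))))
    stop("non-grayscale TIFF: expected single-channel pages")
  d <- dim(pages[[1]])
  pixels <- array(unlist(pages), dim = c(d[1], d[2], length(pages)))
  if (is.null(truth_path)) {
    tp <- default_truth_path(path)
    truth_path <- if (file.exists(tp)) tp else NA
  }
  truth <- if (!is.na(truth_path) && file.exists(truth_path))
    read.csv(truth_path) else NULL
  structure(list(pixels = pixels, truth = truth, px_scale = px_scale,
                 frame_rate_hz = NULL),
            class = "frame_stack")
}

#' Read and write assay tables
#'
#' Assay tables are tab-separated text with columns `group`, optionally
#' `stratum`, `n_tested`, `n_responded`.
#'
#' @param table Assay data frame.
#' @param path File path.
#' @return `write_assay_tsv()` returns `path` invisibly;
#'   `read_assay_tsv()` returns a validated data frame.
#' @export
write_assay_tsv <- function(table, path) {
  if (!all(c("group", "n_tested", "n_responded") %in% names(table)))
    stop("assay table needs columns group, n_tested, n_responded")
  write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_assay_tsv
#' @export
read_assay_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, check.names = FALSE)
  need <- c("group", "n_tested", "n_responded")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("assay table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(!is.finite(tab$n_tested)) || any(!is.finite(tab$n_responded)))
    stop("non-numeric counts in ", path)
  if (any(tab$n_tested < 1) ||
      any(tab$n_responded < 0 | tab$n_responded > tab$n_tested))
    stop("invalid counts in ", path,
         ": need 0 <= n_responded <= n_tested, n_tested >= 1")
  tab
}

#' Write a landmark track as CSV
#'
#' Columns: `frame,eye_x,eye_y,tip_x,tip_y,confidence`.
#'
#' @param track A `landmark_track` from [track_stack()].
#' @param path File path.
#' @export
write_track_csv <- function(track, path) {
  need <- c("frame", "eye_x", "eye_y", "tip_x", "tip_y", "confidence")
  if (!all(need %in% names(track))) stop("not a landmark track")
  write.csv(track[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
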