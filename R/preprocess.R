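#' Filter collapsed reads before normalization
#'
#' Drops reads containing undetermined bases (N), reads with a count of
#' zero, and -- when the length window is enabled -- reads outside
#' `[min_len, max_len]`. sRNA datasets use the 18-30 nt window typical of
#' plant regulatory sRNAs; degradome datasets are filtered with the window
#' disabled (pass `min_len = NULL`), since degradome fragment length is a
#' property of the library preparation, not of the sRNA class.
#'
#' @param reads A reads data.frame from [read_collapsed_reads()].
#' @param min_len,max_len Inclusive length bounds; set both to `NULL` to
#'   disable the length filter.
#' @return The filtered data.frame, original order preserved.
#' @export
filter_reads <- function(reads, min_len = 18L, max_len = 30L) {
  stopifnot(is.data.frame(reads))
  if (!is.null(min_len) && !is.null(max_len) && min_len > max_len) {
    stop("min_len must be <= max_len", call. = FALSE)
  }
  keep <- !grepl("N", reads$sequence, fixed = TRUE) & reads$raw_count > 0
  if (!is.null(min_len) || !is.null(max_len)) {
    len <- nchar(reads$sequence)
    if (!is.null(min_len)) keep <- keep & len >= min_len
    if (!is.null(max_len)) keep <- keep & len <= max_len
  }
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) {
    warning("no reads survive filtering", call. = FALSE)
  }
  out
}

#' Normalize read counts to reads per million (RPM)
#'
#' `rpm = raw_count / total_raw_count * 1e6`, where the total is taken over
#' the reads present in `reads` -- i.e. over reads that survived
#' [filter_reads()]. After normalization the RPM column sums to 1e6.
#'
#' @param reads A filtered reads data.frame.
#' @return The same data.frame with the `rpm` column set.
#' @export
normalize_rpm <- function(reads) {
  total <- sum(as.numeric(reads$raw_count))
  if (total <= 0) stop("cannot normalize: total raw count is 0", call. = FALSE)
  reads$rpm <- reads$raw_count / total * 1e6
  reads
}

#' Summary statistics of a read dataset
#'
#' @param reads A reads data.frame.
#' @return A list with `total_raw_count`, `n_sequences`, and
#'   `length_histogram` (a table of read length).
#' @export
dataset_stats <- function(reads) {
  list(total_raw_count = sum(as.numeric(reads$raw_count)),
       n_sequences = nrow(reads),
       length_histogram = table(nchar(reads$sequence)))
}

#' Standard preprocessing for one dataset
#'
#' [filter_reads()] followed by [normalize_rpm()], with the length window
#' enabled for sRNA data and disabled for degradome data.
#'
#' @param reads A reads data.frame.
#' @param kind `"srna"` or `"degradome"`.
#' @param min_len,max_len Length window used when `kind = "srna"`.
#' @return The filtered, RPM-normalized data.frame.
#' @export
preprocess_reads <- function(reads, kind = c("srna", "degradome"),
                             min_len = 18L, max_len = 30L) {
  kind <- match.arg(kind)
  f <- if (kind == "srna") {
    filter_reads(reads, min_len, max_len)
  } else {
    filter_reads(reads, NULL, NULL)
  }
  if (nrow(f) == 0) return(f)
  normalize_rpm(f)
}
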