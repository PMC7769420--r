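#' Map degradome reads onto transcripts by exact 5'-anchored matching
#'
#' Each degradome read marks, by its 5' end, the first nucleotide of an
#' uncapped degradation fragment. Every exact, full-length occurrence of
#' every read in every transcript is recorded by its 1-based 5'-end
#' position; a read may hit several transcripts and several positions.
#' Matching is exact (no mismatches). Implemented with Biostrings
#' dictionary matching; results are identical to a naive substring search.
#'
#' @param reads A degradome reads data.frame (preprocessed: filtered and
#'   RPM-normalized).
#' @param transcripts A transcripts data.frame from [read_fasta()].
#' @return An object of class `degradome_index`: a list with `hits` (a
#'   data.frame `target_id`, `position`, `sequence`, `raw_count`, `rpm`)
#'   and `transcript_length` (named integer vector).
#' @export
build_index <- function(reads, transcripts) {
  tl <- setNames(nchar(transcripts$sequence), transcripts$id)
  empty <- data.frame(target_id = character(), position = integer(),
                      sequence = character(), raw_count = integer(),
                      rpm = numeric(), stringsAsFactors = FALSE)
  if (nrow(reads) == 0 || nrow(transcripts) == 0) {
    return(structure(list(hits = empty, transcript_length = tl),
                     class = "degradome_index"))
  }
  subjects <- Biostrings::DNAStringSet(setNames(gsub("N", "-", transcripts$sequence,
                                                     fixed = TRUE),
                                                transcripts$id))
  # N never matches anything here, so mask it with a gap letter
  blocks <- list()
  widths <- nchar(reads$sequence)
  for (w in sort(unique(widths))) {
    sel <- which(widths == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(reads$sequence[sel]))
    for (j in seq_len(nrow(transcripts))) {
      m <- Biostrings::matchPDict(pd, subjects[[j]])
      starts <- Biostrings::startIndex(m)
      nhit <- lengths(starts)
      if (sum(nhit) == 0) next
      ri <- rep(sel, nhit)
      blocks[[length(blocks) + 1L]] <- data.frame(
        target_id = transcripts$id[j],
        position = unlist(starts, use.names = FALSE),
        sequence = reads$sequence[ri],
        raw_count = reads$raw_count[ri],
        rpm = reads$rpm[ri],
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(blocks)) do.call(rbind, blocks) else empty
  hits <- hits[order(hits$target_id, hits$position, hits$sequence), ,
               drop = FALSE]
  rownames(hits) <- NULL
  structure(list(hits = hits, transcript_length = tl),
            class = "degradome_index")
}

#' @export
print.degradome_index <- function(x, ...) {
  cat(sprintf("degradome_index: %d hits on %d transcripts (%d indexed)\n",
              nrow(x$hits), length(unique(x$hits$target_id)),
              length(x$transcript_length)))
  invisible(x)
}

transcript_hits <- function(index, target_id) {
  if (!target_id %in% names(index$transcript_length)) {
    stop("unknown transcript '", target_id, "'", call. = FALSE)
  }
  index$hits[index$hits$target_id == target_id, , drop = FALSE]
}

#' Signal intensity of a cleavage site
#'
#' The mean normalized count over the distinct degradome sequences whose 5'
#' end maps exactly at `position`: sum of their RPM divided by their
#' number.
#'
#' @param index A [build_index()] result.
#' @param target_id Transcript id.
#' @param position 1-based transcript coordinate.
#' @return The site signal intensity (RPM).
#' @export
site_intensity <- function(index, target_id, position) {
  h <- transcript_hits(index, target_id)
  at <- h[h$position == position, , drop = FALSE]
  if (nrow(at) == 0) {
    stop("no degradome reads map at ", target_id, ":", position, call. = FALSE)
  }
  sum(at$rpm) / nrow(at)
}

#' Signal intensity of the degraded background
#'
#' The mean normalized count over the distinct degradome sequences mapped
#' to the same transcript whose 5' end is NOT at `position`; 0 when no
#' other sequence maps to the transcript.
#'
#' @inheritParams site_intensity
#' @param include_site_reads If `TRUE`, site reads are kept in the
#'   denominator (alternative reading of the background formula); default
#'   excludes them from numerator and denominator alike.
#' @return The background signal intensity (RPM).
#' @export
background_intensity <- function(index, target_id, position,
                                 include_site_reads = FALSE) {
  h <- transcript_hits(index, target_id)
  off <- h[h$position != position, , drop = FALSE]
  denom <- if (include_site_reads) nrow(h) else nrow(off)
  if (denom == 0) return(0)
  sum(off$rpm) / denom
}

#' Call specific cleavage sites on a transcript
#'
#' Every position with mapped degradome signal is evaluated; a site is
#' specific when its signal is at least `min_ratio` times the background.
#' When the background is exactly zero the ratio is undefined and the site
#' is specific iff its intensity reaches `min_abs_signal` (an absolute
#' floor against single spurious reads).
#'
#' @inheritParams site_intensity
#' @param min_ratio Site/background ratio threshold.
#' @param min_abs_signal Absolute intensity floor used when background = 0.
#' @param include_site_reads Passed to [background_intensity()].
#' @return A data.frame of class kept plain: `target_id`, `position`,
#'   `site_intensity`, `background_intensity`, `ratio` (`Inf` when
#'   background is 0), `specific`; sorted by position.
#' @export
call_sites <- function(index, target_id, min_ratio = 5,
                       min_abs_signal = 1.0, include_site_reads = FALSE) {
  h <- transcript_hits(index, target_id)
  positions <- sort(unique(h$position))
  if (length(positions) == 0) {
    return(data.frame(target_id = character(), position = integer(),
                      site_intensity = numeric(),
                      background_intensity = numeric(),
                      ratio = numeric(), specific = logical(),
                      stringsAsFactors = FALSE))
  }
  si <- vapply(positions, function(p) {
    at <- h$position == p
    sum(h$rpm[at]) / sum(at)
  }, numeric(1))
  bg <- vapply(positions, function(p) {
    off <- h$position != p
    denom <- if (include_site_reads) nrow(h) else sum(off)
    if (denom == 0) 0 else sum(h$rpm[off]) / denom
  }, numeric(1))
  ratio <- ifelse(bg > 0, si / bg, Inf)
  specific <- ifelse(bg > 0, ratio >= min_ratio, si >= min_abs_signal)
  data.frame(target_id = target_id, position = positions,
             site_intensity = si, background_intensity = bg,
             ratio = ratio, specific = specific,
             stringsAsFactors = FALSE)
}

#' Per-position degradome signal (t-plot data)
#'
#' The summed RPM of degradome reads whose 5' end falls at each transcript
#' position -- the data behind a t-plot (signal versus position, with
#' cleavage sites showing as peaks).
#'
#' @inheritParams site_intensity
#' @param all_positions If `TRUE`, include zero-signal positions so the
#'   table spans the whole transcript.
#' @return A data.frame with columns `position` and `signal`.
#' @export
tplot_data <- function(index, target_id, all_positions = FALSE) {
  h <- transcript_hits(index, target_id)
  agg <- if (nrow(h)) {
    r <- rowsum(h$rpm, group = h$position)
    data.frame(position = as.integer(rownames(r)), signal = r[, 1])
  } else {
    data.frame(position = integer(), signal = numeric())
  }
  if (all_positions) {
    full <- data.frame(position = seq_len(index$transcript_length[[target_id]]),
                       signal = 0)
    full$signal[match(agg$position, full$position)] <- agg$signal
    agg <- full
  }
  rownames(agg) <- NULL
  agg
}

#' Write t-plot data for transcripts to CSV files
#'
#' One file per transcript, named `<target_id>.tplot.csv`, with columns
#' `position,signal`.
#'
#' @param index A [build_index()] result.
#' @param dir Output directory (created if needed).
#' @param target_ids Transcripts to export; default all with hits.
#' @return Invisibly, the written paths.
#' @export
write_tplot_csv <- function(index, dir, target_ids = NULL) {
  if (is.null(target_ids)) target_ids <- unique(index$hits$target_id)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(target_ids, function(id) {
    p <- file.path(dir, paste0(id, ".tplot.csv"))
    utils::write.csv(tplot_data(index, id), p, row.names = FALSE, quote = FALSE)
    p
  }, character(1))
  invisible(paths)
}
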