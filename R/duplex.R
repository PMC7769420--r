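#' Scoring configuration for sRNA/target duplex alignment
#'
#' The position-dependent complementarity penalty used to screen candidate
#' binding sites, in the style of the psRNATarget-family rules for plant
#' sRNA targets. sRNA positions are numbered 1..L from the 5' end; the
#' duplex is antiparallel, so sRNA position 1 pairs the 3'-most base of the
#' binding site on the transcript.
#'
#' Penalties (defaults): each G:U wobble 0.5; each mismatch 1.0 inside the
#' seed (positions 2-13) and 0.5 outside it; each bulge event 2.0 plus 0.5
#' per nucleotide beyond the first. An alignment is rejected outright when
#' it has a mismatch at position 10 or 11 (the slicer-site positions), more
#' than two mismatches in the seed (G:U wobbles do not count), more than
#' two bulge events, or a total penalty above `max_score` (5).
#'
#' @param gu_penalty Penalty per G:U wobble pair.
#' @param mm_penalty_seed Penalty per mismatch within the seed.
#' @param mm_penalty_nonseed Penalty per mismatch outside the seed.
#' @param bulge_penalty Penalty per bulge event.
#' @param bulge_extra_nt_penalty Additional penalty per bulged nucleotide
#'   beyond the first within one event.
#' @param max_seed_mismatches Maximum mismatches tolerated in the seed.
#' @param seed_start,seed_end Seed bounds (sRNA positions, inclusive).
#' @param forbidden_mm_positions sRNA positions at which a mismatch rejects
#'   the alignment.
#' @param max_bulges Maximum number of bulge events.
#' @param max_score Maximum total penalty of an acceptable site.
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(gu_penalty = 0.5,
                           mm_penalty_seed = 1.0,
                           mm_penalty_nonseed = 0.5,
                           bulge_penalty = 2.0,
                           bulge_extra_nt_penalty = 0.5,
                           max_seed_mismatches = 2L,
                           seed_start = 2L,
                           seed_end = 13L,
                           forbidden_mm_positions = c(10L, 11L),
                           max_bulges = 2L,
                           max_score = 5.0) {
  stopifnot(gu_penalty >= 0, mm_penalty_seed >= 0, mm_penalty_nonseed >= 0,
            bulge_penalty >= 0, bulge_extra_nt_penalty >= 0,
            max_seed_mismatches >= 0, seed_start >= 1,
            seed_start < seed_end, max_bulges >= 0, max_score > 0)
  structure(list(gu_penalty = gu_penalty,
                 mm_penalty_seed = mm_penalty_seed,
                 mm_penalty_nonseed = mm_penalty_nonseed,
                 bulge_penalty = bulge_penalty,
                 bulge_extra_nt_penalty = bulge_extra_nt_penalty,
                 max_seed_mismatches = as.integer(max_seed_mismatches),
                 seed_start = as.integer(seed_start),
                 seed_end = as.integer(seed_end),
                 forbidden_mm_positions = as.integer(forbidden_mm_positions),
                 max_bulges = as.integer(max_bulges),
                 max_score = max_score),
            class = "scoring_config")
}

#' Pair state of an sRNA base opposite a target base
#'
#' The target base is read on the mRNA sense strand; the duplex is
#' antiparallel, so Watson-Crick means complementarity (A:T, C:G). G:U
#' wobble is sRNA G opposite target T, or sRNA T (U) opposite target G.
#'
#' @param srna_base,target_base Single bases in A/C/G/T (vectorized).
#' @return Character vector over `"WC"`, `"GU"`, `"MM"`.
#' @export
pair_state <- function(srna_base, target_base) {
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  s <- code[toupper(srna_base)]
  t <- code[toupper(target_base)]
  if (anyNA(s) || anyNA(t)) {
    stop("undetermined base in pair_state (bases must be A/C/G/T)",
         call. = FALSE)
  }
  su <- unname(s + t)
  ifelse(su == 3L, "WC", ifelse(su == 5L, "GU", "MM"))
}

#' Score a duplex alignment under the penalty rules
#'
#' Scores an explicit per-position alignment: `pair_states` gives, for each
#' sRNA position 1..L, one of `"WC"`, `"GU"`, `"MM"`, or `"BULGE_SRNA"`
#' (the sRNA base is bulged out); `target_bulges` lists the lengths of
#' target-side bulge events. Each maximal run of `BULGE_SRNA` positions
#' counts as one bulge event.
#'
#' @param pair_states Character vector of per-position states.
#' @param target_bulges Integer vector of target-side bulge lengths
#'   (possibly empty).
#' @param config A [scoring_config()].
#' @return A list with `accepted` (logical), `penalty` (total penalty, also
#'   computed for rejected alignments when finite), and `reason` (`NA` or
#'   why the alignment is rejected).
#' @export
score_alignment <- function(pair_states, target_bulges = integer(),
                            config = scoring_config()) {
  L <- length(pair_states)
  ok_states <- c("WC", "GU", "MM", "BULGE_SRNA")
  if (!all(pair_states %in% ok_states)) {
    stop("pair_states must be over {WC, GU, MM, BULGE_SRNA}", call. = FALSE)
  }
  pos <- seq_len(L)
  in_seed <- pos >= config$seed_start & pos <= config$seed_end
  is_mm <- pair_states == "MM"
  is_gu <- pair_states == "GU"

  # sRNA-side bulge events = maximal runs of BULGE_SRNA
  rl <- rle(pair_states == "BULGE_SRNA")
  srna_bulge_lens <- rl$lengths[rl$values]
  bulge_lens <- c(srna_bulge_lens, as.integer(target_bulges))

  penalty <- sum(is_gu) * config$gu_penalty +
    sum(is_mm & in_seed) * config$mm_penalty_seed +
    sum(is_mm & !in_seed) * config$mm_penalty_nonseed +
    length(bulge_lens) * config$bulge_penalty +
    sum(pmax(bulge_lens - 1L, 0L)) * config$bulge_extra_nt_penalty

  reason <- NA_character_
  if (any(is_mm[pos %in% config$forbidden_mm_positions])) {
    reason <- "mismatch at forbidden position"
  } else if (sum(is_mm & in_seed) > config$max_seed_mismatches) {
    reason <- "too many seed mismatches"
  } else if (length(bulge_lens) > config$max_bulges) {
    reason <- "too many bulges"
  } else if (penalty > config$max_score + 1e-9) {
    reason <- "penalty above max_score"
  }
  list(accepted = is.na(reason), penalty = penalty, reason = reason)
}

#' Find candidate sRNA binding sites on a transcript
#'
#' Aligns the full-length sRNA antiparallel against every transcript
#' segment, allowing up to `max_bulges` internal bulges, and returns all
#' acceptable sites (penalty within `max_score`, no rejection rule hit).
#' One alignment is reported per binding-site start: the minimum-penalty
#' one, ties broken by fewer bulges, then fewer mismatches, then smallest
#' end coordinate. Segments containing N are not scored.
#'
#' @param srna An sRNA sequence (character) or one-row reads data.frame.
#' @param transcript A transcript: `list(id=, sequence=)`, a one-row
#'   data.frame, or a plain sequence (id then `"transcript"`).
#' @param config A [scoring_config()].
#' @return A data.frame with columns `target_id`, `target_start`,
#'   `target_end` (1-based inclusive), `penalty`, `n_bulges`, `n_mismatch`,
#'   `states` (one char per sRNA position: W/G/M/b), `bulges`
#'   (`"S:pos:len;T:pos:len"` events, pos = sRNA position), `pairmap`
#'   (list column: per sRNA position the paired target coordinate, 0 when
#'   bulged), `srna_sequence`; sorted by penalty ascending then start.
#' @export
find_candidate_sites <- function(srna, transcript, config = scoring_config()) {
  if (is.data.frame(srna)) srna <- srna$sequence[1]
  if (is.data.frame(transcript)) {
    transcript <- list(id = transcript$id[1], sequence = transcript$sequence[1])
  } else if (is.character(transcript)) {
    transcript <- list(id = "transcript", sequence = transcript)
  }
  srna <- normalize_seq(srna)
  L <- nchar(srna)
  if (L < config$seed_end) {
    stop("sRNA shorter than the seed region (", config$seed_end, " nt)",
         call. = FALSE)
  }
  if (grepl("[^ACGT]", srna)) {
    stop("sRNA contains undetermined bases", call. = FALSE)
  }
  res <- duplex_scan_cpp(srna, transcript$sequence,
                         config$gu_penalty, config$mm_penalty_seed,
                         config$mm_penalty_nonseed, config$bulge_penalty,
                         config$bulge_extra_nt_penalty,
                         config$max_seed_mismatches,
                         config$seed_start, config$seed_end,
                         config$forbidden_mm_positions,
                         config$max_bulges, config$max_score)
  df <- data.frame(target_id = rep(transcript$id, length(res$target_start)),
                   target_start = res$target_start,
                   target_end = res$target_end,
                   penalty = res$penalty,
                   n_bulges = res$n_bulges,
                   n_mismatch = res$n_mismatch,
                   states = as.character(res$states),
                   bulges = as.character(res$bulges),
                   stringsAsFactors = FALSE)
  df$pairmap <- res$pairmap
  df$srna_sequence <- rep(srna, nrow(df))
  o <- order(df$penalty, df$target_start)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Reverse complement (DNA alphabet)
#'
#' @param x Character vector of sequences over A/C/G/T/N.
#' @return The reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
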