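#' Expected cleavage window of a duplex alignment
#'
#' AGO-guided slicing cuts the target opposite sRNA positions 10/11, so the
#' 5' end of the downstream degradation fragment -- what a degradome read
#' marks -- is the target base paired with sRNA position 10. That position,
#' expanded by `tolerance` on both sides, is where a genuine cleavage
#' signal for this alignment must fall ("the middle of the binding site").
#' Bulges are accounted for through the alignment's base-pair map; if
#' position 10 itself is bulged out, the position is interpolated from the
#' nearest paired position at or after 10.
#'
#' @param alignment One row of a [find_candidate_sites()] result (or a list
#'   with a `pairmap` element).
#' @param tolerance Non-negative integer; the window is the slicer position
#'   +/- `tolerance`.
#' @return Integer vector of transcript positions.
#' @export
expected_cleavage_window <- function(alignment, tolerance = 0L) {
  pm <- if (is.data.frame(alignment)) alignment$pairmap[[1]] else alignment$pairmap
  if (length(pm) < 10) {
    stop("alignment spans fewer than 10 sRNA positions", call. = FALSE)
  }
  p10 <- pm[10]
  if (p10 == 0) {
    j <- which(pm[10:length(pm)] != 0)
    if (length(j) == 0) stop("no paired position at or after 10", call. = FALSE)
    j <- j[1] + 9L
    p10 <- pm[j] + (j - 10L)
  }
  seq.int(p10 - tolerance, p10 + tolerance)
}

#' Extract the 30-nt bait window around a cleavage site
#'
#' The candidate sRNA binding region: the cleavage position as center with
#' 15 nt upstream and 14 nt downstream (the cleaved base being the 16th of
#' the 30), clipped at the transcript ends.
#'
#' @param transcript A transcript (one-row data.frame or
#'   `list(id=, sequence=)`).
#' @param position 1-based cleavage position on the transcript.
#' @return A list of class `bait`: `target_id`, `center`, `window_start`,
#'   `window_end`, `sequence`.
#' @export
extract_bait <- function(transcript, position) {
  if (is.data.frame(transcript)) {
    transcript <- list(id = transcript$id[1], sequence = transcript$sequence[1])
  }
  L <- nchar(transcript$sequence)
  if (position < 1 || position > L) {
    stop("cleavage position ", position, " outside transcript ",
         transcript$id, " (length ", L, ")", call. = FALSE)
  }
  ws <- max(1L, position - 15L)
  we <- min(L, position + 14L)
  structure(list(target_id = transcript$id,
                 center = as.integer(position),
                 window_start = as.integer(ws),
                 window_end = as.integer(we),
                 sequence = substr(transcript$sequence, ws, we)),
            class = "bait")
}

#' Registry of stable identifiers for unannotated sRNAs
#'
#' Novel (unannotated) sRNAs get identifiers `sRNA_<tag>_<n>` in order of
#' first assignment, stable across one run when the same registry is
#' threaded through all calls.
#'
#' @param species_tag Short species tag used in the identifier (e.g.
#'   `"AT"`).
#' @return An environment of class `novel_registry`.
#' @export
new_novel_registry <- function(species_tag = "XX") {
  e <- new.env(parent = emptyenv())
  e$map <- character()
  e$tag <- species_tag
  structure(e, class = "novel_registry")
}

novel_id <- function(registry, sequence) {
  got <- registry$map[sequence]
  if (!is.na(got)) return(unname(got))
  id <- sprintf("sRNA_%s_%d", registry$tag, length(registry$map) + 1L)
  registry$map[sequence] <- id
  id
}

#' Reverse mining: all sRNAs qualified to cleave at a bait's center
#'
#' Every sRNA in the dataset whose duplex with the bait passes the scoring
#' rules AND whose expected cleavage position falls on the bait center
#' (within `tolerance`) is a candidate regulator of the site. Candidates
#' are sorted by expression (RPM) descending; those below
#' `min_expr_fraction` (1/10) of the highest-expressed candidate are
#' flagged as dropped -- cleavage at a shared site is attributed to the
#' strongly expressed qualifiers. Annotated names are attached from
#' `known`; unannotated candidates receive stable novel ids.
#'
#' @param bait A [extract_bait()] result.
#' @param srna_reads Preprocessed (filtered, RPM-normalized) sRNA reads.
#' @param known A `known_annotation` or `NULL`.
#' @param config A [scoring_config()].
#' @param tolerance Cleavage-window half-width (see
#'   [expected_cleavage_window()]).
#' @param min_expr_fraction Expression filter: retained iff
#'   `rpm >= max(rpm) * min_expr_fraction`.
#' @param registry A [new_novel_registry()]; created ad hoc when `NULL`.
#' @return A data.frame, one row per candidate co-regulator, sorted by RPM
#'   descending (ties by sequence): `sequence`, `raw_count`, `rpm`, `name`
#'   (comma-joined known names, or the novel id), `known` (logical),
#'   `penalty`, `n_bulges`, `n_mismatch`, `states`, `target_start`,
#'   `target_end` (transcript coordinates of the binding site), `retained`.
#' @export
reverse_dig <- function(bait, srna_reads, known = NULL,
                        config = scoring_config(), tolerance = 0L,
                        min_expr_fraction = 0.1, registry = NULL) {
  stopifnot(inherits(bait, "bait"))
  if (is.null(registry)) registry <- new_novel_registry()
  empty <- data.frame(sequence = character(), raw_count = integer(),
                      rpm = numeric(), name = character(), known = logical(),
                      penalty = numeric(), n_bulges = integer(),
                      n_mismatch = integer(), states = character(),
                      target_start = integer(), target_end = integer(),
                      retained = logical(), stringsAsFactors = FALSE)
  if (nrow(srna_reads) == 0) return(empty)

  center_local <- bait$center - bait$window_start + 1L
  hits <- vector("list", nrow(srna_reads))
  for (k in seq_len(nrow(srna_reads))) {
    sq <- srna_reads$sequence[k]
    if (nchar(sq) < config$seed_end || grepl("[^ACGT]", sq)) next
    res <- duplex_scan_cpp(sq, bait$sequence,
                           config$gu_penalty, config$mm_penalty_seed,
                           config$mm_penalty_nonseed, config$bulge_penalty,
                           config$bulge_extra_nt_penalty,
                           config$max_seed_mismatches,
                           config$seed_start, config$seed_end,
                           config$forbidden_mm_positions,
                           config$max_bulges, config$max_score)
    if (length(res$target_start) == 0) next
    # best alignment whose slicer position hits the bait center
    for (a in order(res$penalty, res$target_start)) {
      pm <- res$pairmap[[a]]
      p10 <- pm[10]
      if (p10 == 0) {
        jj <- which(pm[10:length(pm)] != 0)
        if (length(jj) == 0) next
        jj <- jj[1] + 9L
        p10 <- pm[jj] + (jj - 10L)
      }
      if (abs(p10 - center_local) <= tolerance) {
        hits[[k]] <- list(k = k, a = a, res = res)
        break
      }
    }
  }
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (length(hits) == 0) return(empty)
  co <- do.call(rbind, lapply(hits, function(h) {
    k <- h$k; a <- h$a; res <- h$res
    data.frame(
      sequence = srna_reads$sequence[k],
      raw_count = srna_reads$raw_count[k],
      rpm = srna_reads$rpm[k],
      penalty = res$penalty[a],
      n_bulges = res$n_bulges[a],
      n_mismatch = res$n_mismatch[a],
      states = as.character(res$states[a]),
      target_start = res$target_start[a] + bait$window_start - 1L,
      target_end = res$target_end[a] + bait$window_start - 1L,
      stringsAsFactors = FALSE)
  }))
  co <- co[order(-co$rpm, co$sequence), , drop = FALSE]
  rownames(co) <- NULL

  nm <- lookup_known(known, co$sequence)
  co$known <- lengths(nm) > 0
  co$name <- vapply(seq_len(nrow(co)), function(i) {
    if (co$known[i]) paste(nm[[i]], collapse = ",")
    else novel_id(registry, co$sequence[i])
  }, character(1))
  co$retained <- co$rpm >= max(co$rpm) * min_expr_fraction
  co[, c("sequence", "raw_count", "rpm", "name", "known", "penalty",
         "n_bulges", "n_mismatch", "states", "target_start", "target_end",
         "retained")]
}

#' Forward mining: targets of a query sRNA, validated by degradome and
#' reverse mining
#'
#' For each transcript, candidate binding sites of the query sRNA are
#' scanned ([find_candidate_sites()]); specific degradome cleavage sites
#' ([call_sites()]) falling in each alignment's expected cleavage window
#' survive; around each surviving site a 30-nt bait is extracted and
#' [reverse_dig()] recovers every qualifying sRNA. The pair is confirmed
#' when the query itself is recovered and retained by the expression
#' filter -- i.e. the forward call is cross-validated by the reverse
#' direction. Pairs whose query is recovered but expression-dropped (or,
#' pathologically, not recovered) are returned with `confirmed = FALSE`
#' for the rejected-pairs report.
#'
#' @param query_srna Query sRNA sequence (character) or one-row reads
#'   data.frame.
#' @param transcripts Transcripts data.frame.
#' @param degradome_index A [build_index()] result over the same
#'   transcripts (reads preprocessed).
#' @param srna_reads Preprocessed sRNA HTS reads (for reverse mining).
#' @param known A `known_annotation` or `NULL`.
#' @param config A [scoring_config()].
#' @param min_ratio,min_abs_signal Cleavage-site thresholds
#'   ([call_sites()]).
#' @param tolerance Cleavage-window half-width.
#' @param min_expr_fraction Expression filter for co-regulators.
#' @param source_label Dataset/tissue label carried into the results.
#' @param registry Optional [new_novel_registry()].
#' @return A list of `target_pair` objects; each has `query_sequence`,
#'   `target_id`, `alignment` (one-row data.frame), `site` (one-row
#'   data.frame), `co_regulators` (data.frame, `is_query` column added),
#'   `confirmed`, `source_label`.
#' @export
forward_dig <- function(query_srna, transcripts, degradome_index, srna_reads,
                        known = NULL, config = scoring_config(),
                        min_ratio = 5, min_abs_signal = 1.0,
                        tolerance = 0L, min_expr_fraction = 0.1,
                        source_label = "dataset", registry = NULL) {
  if (is.data.frame(query_srna)) query_srna <- query_srna$sequence[1]
  query_srna <- normalize_seq(query_srna)
  if (grepl("[^ACGT]", query_srna)) {
    stop("query sRNA contains undetermined bases", call. = FALSE)
  }
  if (is.null(registry)) registry <- new_novel_registry()

  pairs <- list()
  for (j in seq_len(nrow(transcripts))) {
    tr <- transcripts[j, ]
    cands <- find_candidate_sites(query_srna, tr, config)
    if (nrow(cands) == 0) next
    sites <- call_sites(degradome_index, tr$id, min_ratio, min_abs_signal)
    sites <- sites[sites$specific, , drop = FALSE]
    if (nrow(sites) == 0) next
    # one pair per cleavage site: the best alignment (candidates are sorted
    # by penalty, then start) whose expected window contains the site wins;
    # bulged shoulder variants of the same binding event are absorbed
    best_for_site <- rep(NA_integer_, nrow(sites))
    for (a in seq_len(nrow(cands))) {
      win <- expected_cleavage_window(cands[a, ], tolerance)
      match_s <- which(sites$position %in% win & is.na(best_for_site))
      best_for_site[match_s] <- a
    }
    for (s in which(!is.na(best_for_site))) {
      {
        a <- best_for_site[s]
        site <- sites[s, ]
        bait <- extract_bait(tr, site$position)
        co <- reverse_dig(bait, srna_reads, known, config, tolerance,
                          min_expr_fraction, registry)
        co$is_query <- co$sequence == query_srna
        confirmed <- any(co$is_query & co$retained)
        pairs[[length(pairs) + 1L]] <- structure(
          list(query_sequence = query_srna,
               target_id = tr$id,
               alignment = cands[a, ],
               site = site,
               co_regulators = co,
               confirmed = confirmed,
               source_label = source_label),
          class = "target_pair")
      }
    }
  }
  pairs
}

#' @export
print.target_pair <- function(x, ...) {
  cat(sprintf(
    "target_pair: %s @ %s:%d-%d (penalty %.1f), cleavage %d (ratio %.2f), %d co-regulator(s), %s [%s]\n",
    x$query_sequence, x$target_id, x$alignment$target_start,
    x$alignment$target_end, x$alignment$penalty, x$site$position,
    x$site$ratio, nrow(x$co_regulators),
    if (x$confirmed) "CONFIRMED" else "not confirmed", x$source_label))
  invisible(x)
}

#' Aggregate target pairs across tissues/datasets
#'
#' Pairs are keyed by (query sRNA sequence, target id, binding-site start).
#' Expression is tissue-specific, so a regulatory relationship counts as
#' confirmed overall when it is confirmed in at least one dataset;
#' per-dataset evidence is preserved.
#'
#' @param per_dataset_pairs A named list: source label -> list of
#'   `target_pair` objects (e.g. one [forward_dig()] result per tissue).
#' @return A list of `target_pair_agg` objects, sorted by target id,
#'   binding-site start, query sequence. Each has `query_sequence`,
#'   `target_id`, `target_start`, `confirmed` (any dataset), `evidence`
#'   (named list of `target_pair` by source label).
#' @export
aggregate_tissues <- function(per_dataset_pairs) {
  recs <- list()
  for (lab in names(per_dataset_pairs)) {
    for (p in per_dataset_pairs[[lab]]) {
      key <- paste(p$query_sequence, p$target_id, p$alignment$target_start,
                   sep = "\r")
      if (is.null(recs[[key]])) {
        recs[[key]] <- structure(
          list(query_sequence = p$query_sequence,
               target_id = p$target_id,
               target_start = p$alignment$target_start,
               confirmed = FALSE,
               evidence = list()),
          class = "target_pair_agg")
      }
      recs[[key]]$confirmed <- recs[[key]]$confirmed || p$confirmed
      recs[[key]]$evidence[[lab]] <- p
    }
  }
  out <- unname(recs)
  if (length(out) > 1) {
    o <- order(vapply(out, `[[`, character(1), "target_id"),
               vapply(out, `[[`, integer(1), "target_start"),
               vapply(out, `[[`, character(1), "query_sequence"))
    out <- out[o]
  }
  out
}
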