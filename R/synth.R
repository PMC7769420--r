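#' Deterministic synthetic fixture generator
#'
#' @description
#' Builds a complete, internally consistent dataset for exercising the full
#' mining pipeline without any downloads: random transcripts with planted
#' sRNA binding sites of engineered penalty, abundance-collapsed sRNA
#' datasets containing the planted sRNAs plus random decoys, degradome
#' datasets with a dominant peak read at each planted site's expected
#' cleavage position over a uniform low background, and a truth table
#' stating, from the planted parameters alone, which pairs the pipeline
#' must confirm.
#'
#' @details
#' Engineered deviation patterns (sRNA positions from the 5' end):
#' \describe{
#'   \item{`perfect`}{full complementarity, penalty 0.}
#'   \item{`gu5`}{one G:U wobble at position 5, penalty 0.5.}
#'   \item{`mm16`}{one non-seed mismatch at position 16, penalty 0.5.}
#'   \item{`bulge1`}{one 1-nt target-side bulge after position 15,
#'     penalty 2.}
#'   \item{`score5`}{G:U at 5, 7, 16, 17, seed mismatches at 3 and 8,
#'     non-seed mismatches at 19 and 20: penalty exactly 5 -- the
#'     acceptance boundary.}
#'   \item{`score5p5`}{as `score5` plus G:U at position 14, penalty 5.5 --
#'     rejected by the score cap.}
#' }
#' Every planted site is verified after embedding: the scan of the host
#' transcript must report exactly the engineered alignment (penalty and
#' slicer position) at the planted start -- and, for rejected patterns,
#' no acceptable alignment pointing at the planted cleavage position.
#' If embedding creates a cheaper accidental alignment the pair is redrawn
#' from the (deterministic) random stream, up to 100 attempts.
#' Background degradome fragments avoid peak positions and duplicate
#' sequences, so the site/background ratio of a planted peak is exactly
#' `peak_count / background_count`.
#'
#' @param n_transcripts Number of transcripts (must be >= `n_planted`;
#'   pair i is planted on transcript i).
#' @param transcript_len Transcript length (nt).
#' @param n_planted Number of planted sRNA-target interactions.
#' @param n_decoy_srnas Random decoy sRNAs per sRNA dataset.
#' @param peak_to_background Default peak/background count ratio.
#' @param background_count Raw count of each background degradome read.
#' @param n_background Background degradome fragments per transcript.
#' @param srna_length Planted sRNA length.
#' @param frag_len Degradome fragment length (PARE-style short signature).
#' @param datasets Character vector of dataset (tissue) labels.
#' @param seed Master seed; all randomness derives from it.
#' @param plan Optional per-pair plan: data.frame with columns `pattern`,
#'   `displacement` (peak offset in nt from the expected cleavage
#'   position), `query_count`, `coreg_count` (0 = no planted co-regulator;
#'   otherwise the count of one co-regulating sRNA variant), `peak_count`.
#'   Defaults: patterns cycling over perfect/gu5/mm16/bulge1, displacement
#'   0, query_count 1000, coreg_count 0, peak_count
#'   `background_count * peak_to_background`.
#' @param min_ratio,tolerance,min_expr_fraction,config Pipeline thresholds
#'   used to fill `expected_confirmed` in the truth table.
#' @return A list of class `synthetic_data`: `transcripts` (data.frame),
#'   `srna` (named list of reads data.frames, raw counts, not normalized),
#'   `degradome` (likewise), `truth` (data.frame, one row per planted
#'   pair), `known` (a `known_annotation` naming each planted query
#'   `syn-miR<i>`), and `params`.
#' @export
generate_synthetic_data <- function(n_transcripts = 12L,
                                    transcript_len = 500L,
                                    n_planted = 10L,
                                    n_decoy_srnas = 300L,
                                    peak_to_background = 20,
                                    background_count = 5L,
                                    n_background = 25L,
                                    srna_length = 21L,
                                    frag_len = 20L,
                                    datasets = "tissue1",
                                    seed = 1L,
                                    plan = NULL,
                                    min_ratio = 5,
                                    tolerance = 0L,
                                    min_expr_fraction = 0.1,
                                    config = scoring_config()) {
  stopifnot(n_transcripts >= n_planted, transcript_len >= 120,
            srna_length >= config$seed_end, frag_len >= 10)
  if (is.null(plan)) {
    plan <- data.frame(
      pattern = rep(c("perfect", "gu5", "mm16", "bulge1"),
                    length.out = n_planted),
      displacement = rep(0L, n_planted),
      query_count = rep(1000L, n_planted),
      coreg_count = rep(0L, n_planted),
      peak_count = rep(as.integer(round(background_count *
                                          peak_to_background)), n_planted),
      stringsAsFactors = FALSE)
  }
  stopifnot(nrow(plan) == n_planted)
  if (is.null(plan$pattern)) plan$pattern <- "perfect"
  if (is.null(plan$displacement)) plan$displacement <- 0L
  if (is.null(plan$query_count)) plan$query_count <- 1000L
  if (is.null(plan$coreg_count)) plan$coreg_count <- 0L
  if (is.null(plan$peak_count)) {
    plan$peak_count <- as.integer(round(background_count * peak_to_background))
  }

  sub_seed <- function(k) as.integer(((seed %% 1000003) * 2039 + k) %% 2147483629)

  transcripts <- with_seed(sub_seed(1L), {
    data.frame(id = sprintf("SYN%03d", seq_len(n_transcripts)),
               sequence = vapply(seq_len(n_transcripts), function(i) {
                 paste(sample(c("A", "C", "G", "T"), transcript_len,
                              replace = TRUE), collapse = "")
               }, character(1)),
               stringsAsFactors = FALSE)
  })

  truth_rows <- vector("list", n_planted)
  coreg_seqs <- rep(NA_character_, n_planted)
  if (n_planted > 0) with_seed(sub_seed(2L), {
    for (i in seq_len(n_planted)) {
      spec <- pattern_spec(plan$pattern[i])
      planted <- NULL
      co_seq <- NA_character_
      for (attempt in seq_len(100L)) {
        cand <- plant_site(transcripts$sequence[i], transcripts$id[i],
                           srna_length, spec, config)
        if (is.null(cand)) next
        co_try <- NA_character_
        if (plan$coreg_count[i] > 0) {
          co_try <- make_coreg(cand, config)
          if (is.na(co_try)) next
        }
        # no cross-talk: this pair's sRNAs must not qualify at any earlier
        # planted site, and no earlier sRNA may qualify at this new site
        ok <- TRUE
        for (j in seq_len(i - 1L)) {
          tr_j <- truth_rows[[j]]
          for (sq in c(cand$srna, co_try)) {
            if (!is.na(sq) &&
                srna_targets_site(sq, transcripts$sequence[j],
                                  tr_j$expected_cleavage_pos, config,
                                  tolerance)) { ok <- FALSE; break }
          }
          if (!ok) break
          for (sq in c(tr_j$srna_sequence, coreg_seqs[j])) {
            if (!is.na(sq) &&
                srna_targets_site(sq, cand$sequence, cand$p10, config,
                                  tolerance)) { ok <- FALSE; break }
          }
          if (!ok) break
        }
        if (ok) { planted <- cand; co_seq <- co_try; break }
      }
      if (is.null(planted)) {
        stop("could not plant pattern '", plan$pattern[i], "' on transcript ",
             transcripts$id[i], " after 100 attempts", call. = FALSE)
      }
      transcripts$sequence[i] <- planted$sequence
      coreg_seqs[i] <- co_seq
      truth_rows[[i]] <- data.frame(
        pair_id = sprintf("P%02d", i),
        target_id = transcripts$id[i],
        srna_sequence = planted$srna,
        coreg_sequence = NA_character_,
        target_start = planted$start,
        target_end = planted$end,
        expected_cleavage_pos = planted$p10,
        peak_pos = planted$p10 + plan$displacement[i],
        pattern = plan$pattern[i],
        penalty = spec$penalty,
        duplex_accepted = spec$accepted,
        peak_count = plan$peak_count[i],
        background_count = background_count,
        displacement = plan$displacement[i],
        query_count = plan$query_count[i],
        coreg_count = plan$coreg_count[i],
        stringsAsFactors = FALSE)
    }
  })
  truth <- if (n_planted > 0) do.call(rbind, truth_rows) else
    data.frame(pair_id = character(), target_id = character(),
               srna_sequence = character(), coreg_sequence = character(),
               target_start = integer(), target_end = integer(),
               expected_cleavage_pos = integer(), peak_pos = integer(),
               pattern = character(), penalty = numeric(),
               duplex_accepted = logical(), peak_count = integer(),
               background_count = integer(), displacement = integer(),
               query_count = integer(), coreg_count = integer(),
               expected_confirmed = logical(), stringsAsFactors = FALSE)
  if (n_planted > 0) truth$coreg_sequence <- coreg_seqs

  # expected outcome, computable from the planted parameters alone
  if (n_planted > 0) {
    max_cand <- pmax(truth$query_count, truth$coreg_count)
    truth$expected_confirmed <- truth$duplex_accepted &
      (truth$peak_count / truth$background_count >= min_ratio) &
      (abs(truth$displacement) <= tolerance) &
      (truth$query_count >= max_cand * min_expr_fraction)
  }

  degradome <- list()
  srna <- list()
  for (d in seq_along(datasets)) {
    lab <- datasets[d]
    degradome[[lab]] <- with_seed(sub_seed(100L + d), {
      make_degradome(transcripts, truth, background_count, n_background,
                     frag_len, lab)
    })
    srna[[lab]] <- with_seed(sub_seed(200L + d), {
      make_srna_dataset(truth, coreg_seqs, n_decoy_srnas, srna_length, lab)
    })
  }

  known <- NULL
  if (n_planted > 0) {
    map <- split(sprintf("syn-miR%d", seq_len(n_planted)),
                 truth$srna_sequence)
    map <- map[unique(truth$srna_sequence)]
    known <- structure(as.list(map), class = "known_annotation",
                       species_prefix = "syn-")
  }

  structure(list(transcripts = transcripts, srna = srna,
                 degradome = degradome, truth = truth, known = known,
                 params = list(n_transcripts = n_transcripts,
                               transcript_len = transcript_len,
                               n_planted = n_planted,
                               n_decoy_srnas = n_decoy_srnas,
                               peak_to_background = peak_to_background,
                               background_count = background_count,
                               n_background = n_background,
                               srna_length = srna_length,
                               frag_len = frag_len,
                               datasets = datasets, seed = seed,
                               min_ratio = min_ratio, tolerance = tolerance,
                               min_expr_fraction = min_expr_fraction)),
            class = "synthetic_data")
}

#' @export
print.synthetic_data <- function(x, ...) {
  cat(sprintf(
    "synthetic_data: %d transcripts, %d planted pairs (%d expected confirmed), %d dataset(s), seed %d\n",
    nrow(x$transcripts), nrow(x$truth),
    if (nrow(x$truth)) sum(x$truth$expected_confirmed) else 0L,
    length(x$params$datasets), x$params$seed))
  invisible(x)
}

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}

pattern_spec <- function(pattern) {
  switch(pattern,
    perfect  = list(gu = integer(), mm = integer(), tb = integer(),
                    penalty = 0.0, accepted = TRUE),
    gu5      = list(gu = 5L, mm = integer(), tb = integer(),
                    penalty = 0.5, accepted = TRUE),
    mm16     = list(gu = integer(), mm = 16L, tb = integer(),
                    penalty = 0.5, accepted = TRUE),
    bulge1   = list(gu = integer(), mm = integer(), tb = 15L,
                    penalty = 2.0, accepted = TRUE),
    score5   = list(gu = c(5L, 7L, 16L, 17L), mm = c(3L, 8L, 19L, 20L),
                    tb = integer(), penalty = 5.0, accepted = TRUE),
    score5p5 = list(gu = c(5L, 7L, 14L, 16L, 17L), mm = c(3L, 8L, 19L, 20L),
                    tb = integer(), penalty = 5.5, accepted = FALSE),
    stop("unknown planted pattern '", pattern, "'", call. = FALSE))
}

# draw an sRNA, build the engineered binding segment, embed it, verify
plant_site <- function(tr_seq, tr_id, srna_length, spec, config) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  s <- sample(c("A", "C", "G", "T"), srna_length, replace = TRUE)
  s[spec$gu] <- sample(c("G", "T"), length(spec$gu), replace = TRUE)
  srna <- paste(s, collapse = "")

  seg <- character(0)
  pair_seg <- integer(srna_length)
  for (i in srna_length:1) {
    if (i %in% spec$tb) {
      seg <- c(seg, sample(c("A", "C", "G", "T"), 1L))   # bulged target nt
    }
    base <- comp[[s[i]]]
    if (i %in% spec$gu) base <- if (s[i] == "G") "T" else "G"
    if (i %in% spec$mm) base <- s[i]
    seg <- c(seg, base)
    pair_seg[i] <- length(seg)
  }
  seg_len <- length(seg)
  L <- nchar(tr_seq)
  start <- sample(seq.int(40L, L - 40L - seg_len), 1L)
  end <- start + seg_len - 1L
  new_seq <- paste0(substr(tr_seq, 1, start - 1L),
                    paste(seg, collapse = ""),
                    substr(tr_seq, end + 1L, L))
  p10 <- start + pair_seg[10L] - 1L

  scan <- find_candidate_sites(srna, list(id = tr_id, sequence = new_seq),
                               config)
  p10s <- vapply(seq_len(nrow(scan)), function(a) {
    win <- expected_cleavage_window(scan[a, ], 0L)
    win[1]
  }, integer(1))
  if (spec$accepted) {
    # forward mining keeps, per cleavage site, the first alignment in
    # (penalty, start) order whose window hits it -- that must be the
    # engineered one, at its engineered penalty
    sel <- which(p10s == p10)
    ok <- length(sel) >= 1 &&
      scan$target_start[sel[1]] == start &&
      abs(scan$penalty[sel[1]] - spec$penalty) < 1e-9
  } else {
    ok <- !any(scan$target_start == start) && !any(p10s == p10)
  }
  if (!ok) return(NULL)
  list(sequence = new_seq, srna = srna, s = s, start = start, end = end,
       p10 = p10, pair_seg = pair_seg, seg = seg, tr_id = tr_id)
}

# does this sRNA have any acceptable alignment whose slicer position falls
# on `center` (within the tolerance) of the given transcript?
srna_targets_site <- function(srna, tr_seq, center, config, tolerance = 0L) {
  scan <- find_candidate_sites(srna, list(id = "x", sequence = tr_seq),
                               config)
  for (a in seq_len(nrow(scan))) {
    if (center %in% expected_cleavage_window(scan[a, ], tolerance)) {
      return(TRUE)
    }
  }
  FALSE
}

# a co-regulating variant: same site, one extra non-seed deviation at
# position 16 (mismatch against the already-planted target base);
# NA when the variant does not verify at the planted site
make_coreg <- function(planted, config) {
  s2 <- planted$s
  tb <- planted$seg[planted$pair_seg[16L]]      # target base opposite pos 16
  cand <- setdiff(c("A", "C", "G", "T"), s2[16L])
  states <- pair_state(cand, rep(tb, length(cand)))
  pick <- cand[states != "WC"][1]               # GU or MM, never restore WC
  s2[16L] <- pick
  co <- paste(s2, collapse = "")
  if (!srna_targets_site(co, planted$sequence, planted$p10, config)) {
    return(NA_character_)
  }
  co
}

make_degradome <- function(transcripts, truth, background_count,
                           n_background, frag_len, label) {
  rows <- list()
  peak_by_tr <- split(truth$peak_pos, truth$target_id)
  for (j in seq_len(nrow(transcripts))) {
    id <- transcripts$id[j]
    seqj <- transcripts$sequence[j]
    L <- nchar(seqj)
    peaks <- peak_by_tr[[id]]
    if (!is.null(peaks)) {
      pk <- truth[truth$target_id == id, , drop = FALSE]
      for (r in seq_len(nrow(pk))) {
        frag <- substr(seqj, pk$peak_pos[r], pk$peak_pos[r] + frag_len - 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = frag, raw_count = pk$peak_count[r],
          stringsAsFactors = FALSE)
      }
    }
    avoid <- unique(c(peaks, truth$expected_cleavage_pos[truth$target_id == id]))
    pool <- setdiff(seq_len(L - frag_len + 1L), avoid)
    bgpos <- sample(pool, min(n_background, length(pool)))
    frags <- substring(seqj, bgpos, bgpos + frag_len - 1L)
    frags <- unique(frags)
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = frags, raw_count = background_count,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  # collapse accidental duplicates across transcripts; keep peaks analytic
  # by dropping duplicated background sequences instead of summing them
  df <- df[!duplicated(df$sequence), , drop = FALSE]
  df$rpm <- 0
  df$source_label <- label
  rownames(df) <- NULL
  df[, c("sequence", "raw_count", "rpm", "source_label")]
}

make_srna_dataset <- function(truth, coreg_seqs, n_decoy, srna_length,
                              label) {
  rows <- list()
  if (nrow(truth) > 0) {
    rows[[1]] <- data.frame(sequence = truth$srna_sequence,
                            raw_count = truth$query_count,
                            stringsAsFactors = FALSE)
    has_co <- which(!is.na(coreg_seqs) & truth$coreg_count > 0)
    if (length(has_co)) {
      rows[[2]] <- data.frame(sequence = coreg_seqs[has_co],
                              raw_count = truth$coreg_count[has_co],
                              stringsAsFactors = FALSE)
    }
  }
  planted <- unlist(lapply(rows, `[[`, "sequence"))
  decoys <- character(0)
  while (length(decoys) < n_decoy) {
    need <- n_decoy - length(decoys)
    new <- vapply(seq_len(need), function(k) {
      paste(sample(c("A", "C", "G", "T"), srna_length, replace = TRUE),
            collapse = "")
    }, character(1))
    decoys <- unique(c(decoys, setdiff(new, planted)))
  }
  rows[[length(rows) + 1L]] <- data.frame(
    sequence = decoys,
    raw_count = sample(1:50, length(decoys), replace = TRUE),
    stringsAsFactors = FALSE)
  df <- do.call(rbind, rows)
  df <- df[!duplicated(df$sequence), , drop = FALSE]
  df$rpm <- 0
  df$source_label <- label
  rownames(df) <- NULL
  df[, c("sequence", "raw_count", "rpm", "source_label")]
}

#' Write a synthetic dataset to a directory of FASTA/TSV files
#'
#' Emits `transcripts.fa`, one `srna_<label>.fa` and `degradome_<label>.fa`
#' per dataset (x_suffix collapsed FASTA), `known_mature.fa`, and
#' `truth_table.tsv`.
#'
#' @param sim A [generate_synthetic_data()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_synthetic_data <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$transcripts, file.path(dir, "transcripts.fa"))
  for (lab in names(sim$srna)) {
    write_collapsed_reads(sim$srna[[lab]],
                          file.path(dir, paste0("srna_", lab, ".fa")),
                          "x_suffix")
    write_collapsed_reads(sim$degradome[[lab]],
                          file.path(dir, paste0("degradome_", lab, ".fa")),
                          "x_suffix")
  }
  if (!is.null(sim$known)) {
    nm <- unlist(sim$known)
    sq <- rep(names(sim$known), lengths(sim$known))
    writeLines(as.vector(rbind(paste0(">", nm), chartr("T", "U", sq))),
               file.path(dir, "known_mature.fa"))
  }
  utils::write.table(sim$truth, file.path(dir, "truth_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
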