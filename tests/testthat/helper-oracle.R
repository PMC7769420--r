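# Independent oracles used by the test-suite.
#
# oracle_scan(): exhaustive enumeration of every duplex alignment of a full
# sRNA against every transcript segment -- all placements of up to
# max_bulges bulge events, every event length the score budget allows --
# scored by direct arithmetic. Per-position contributions are packed into
# one numeric code (penalty half-units + seed-mismatch count * 128 +
# mismatch count * 4096 + a large reject flag) so a whole configuration can
# be evaluated for all segment ends at once with vector slice additions.
# Only supports the default half-unit penalty scheme.

.oracle_geom_cache <- new.env(parent = emptyenv())

# bulge-event geometry (paired-position offsets, counts, constant penalty)
# depends only on the sRNA length and the scoring config defaults, so it is
# cached per length across instances
oracle_geometry <- function(L, cfg) {
  key <- sprintf("L%d", L)
  got <- .oracle_geom_cache[[key]]
  if (!is.null(got)) return(got)

  # every allowed set of bulge events
  lmax1 <- 1 + max(0, floor((cfg$max_score - cfg$bulge_penalty) /
                              cfg$bulge_extra_nt_penalty + 1e-9))
  ltot2 <- if (cfg$max_bulges >= 2 &&
               2 * cfg$bulge_penalty <= cfg$max_score + 1e-9) {
    2 + max(0, floor((cfg$max_score - 2 * cfg$bulge_penalty) /
                       cfg$bulge_extra_nt_penalty + 1e-9))
  } else 0
  configs <- list(list(S = list(), T = list()))
  if (cfg$max_bulges >= 1 && cfg$bulge_penalty <= cfg$max_score + 1e-9) {
    for (l1 in seq_len(min(lmax1, L - 2))) {
      for (j in 2:(L - l1)) {
        configs[[length(configs) + 1L]] <- list(S = list(c(j, l1)), T = list())
      }
      for (jn in 1:(L - 1)) {
        configs[[length(configs) + 1L]] <- list(S = list(), T = list(c(jn, l1)))
      }
    }
  }
  if (cfg$max_bulges >= 2 && ltot2 >= 2) {
    for (l1 in 1:(ltot2 - 1)) for (l2 in 1:(ltot2 - l1)) {
      # S+S: ranges separated by at least one paired position
      for (j1 in 2:(L - l1)) {
        j2min <- j1 + l1 + 1
        if (j2min <= L - l2) for (j2 in j2min:(L - l2)) {
          configs[[length(configs) + 1L]] <-
            list(S = list(c(j1, l1), c(j2, l2)), T = list())
        }
      }
      # T+T: distinct junctions (same junction would be one longer event)
      for (j1 in 1:(L - 2)) for (j2 in (j1 + 1):(L - 1)) {
        configs[[length(configs) + 1L]] <-
          list(S = list(), T = list(c(j1, l1), c(j2, l2)))
      }
      # one S + one T
      for (j1 in 2:(L - l1)) for (j2 in 1:(L - 1)) {
        configs[[length(configs) + 1L]] <-
          list(S = list(c(j1, l1)), T = list(c(j2, l2)))
      }
    }
  }

  geoms <- lapply(configs, function(cf) {
    sbul <- integer(L)
    for (ev in cf$S) sbul[ev[1]:(ev[1] + ev[2] - 1)] <- 1L
    tb <- numeric(L)
    for (ev in cf$T) tb[ev[1]] <- tb[ev[1]] + ev[2]
    t_before <- cumsum(c(0, tb[seq_len(L - 1)]))
    s_before <- cumsum(c(0, sbul[seq_len(L - 1)]))
    o <- (seq_len(L) - 1) + t_before - s_before
    o[sbul == 1L] <- NA
    nb <- length(cf$S) + length(cf$T)
    lens <- c(vapply(cf$S, `[`, numeric(1), 2),
              vapply(cf$T, `[`, numeric(1), 2))
    bconst2 <- 2 * (nb * cfg$bulge_penalty +
                      sum(pmax(lens - 1, 0)) * cfg$bulge_extra_nt_penalty)
    list(o = o, paired = which(!is.na(o)), oL = o[L], nb = nb,
         bconst2 = bconst2)
  })
  .oracle_geom_cache[[key]] <- geoms
  geoms
}

oracle_scan <- function(srna, target, cfg = scoring_config()) {
  stopifnot(!grepl("[^ACGT]", srna), !grepl("[^ACGT]", target))
  code <- c(A = 0, C = 1, G = 2, T = 3)
  sc <- unname(code[strsplit(srna, "")[[1]]])
  tc <- unname(code[strsplit(target, "")[[1]]])
  L <- length(sc)
  Tn <- length(tc)
  REJ <- 2^40

  packmat <- matrix(0, nrow = L, ncol = Tn)
  for (i in seq_len(L)) {
    su <- sc[i] + tc
    gu <- su == 5
    mm <- !(su == 3 | gu)
    in_seed <- i >= cfg$seed_start && i <= cfg$seed_end
    pen2 <- gu * cfg$gu_penalty * 2 +
      mm * 2 * (if (in_seed) cfg$mm_penalty_seed else cfg$mm_penalty_nonseed)
    v <- pen2 + mm * (if (in_seed) 128 else 0) + mm * 4096
    if (i %in% cfg$forbidden_mm_positions) v <- v + mm * REJ
    packmat[i, ] <- v
  }

  geoms <- oracle_geometry(L, cfg)

  best <- rep(Inf, Tn)
  for (g in geoms) {
    n <- Tn - g$oL
    if (n < 1) next
    o <- g$o
    acc <- numeric(n)
    for (i in g$paired) {
      acc <- acc + packmat[i, (g$oL - o[i] + 1):(Tn - o[i])]
    }
    pen2 <- acc %% 128 + g$bconst2
    seedmm <- floor((acc %% 4096) / 128)
    mmn <- floor((acc %% REJ) / 4096)
    ok <- acc < REJ & pen2 <= cfg$max_score * 2 + 1e-9 &
      seedmm <= cfg$max_seed_mismatches
    key <- ifelse(ok, pen2 * 2^24 + g$nb * 2^20 + mmn, Inf)
    best[seq_len(n)] <- pmin(best[seq_len(n)], key)
  }

  sel <- which(is.finite(best))
  data.frame(target_start = sel,
             penalty = floor(best[sel] / 2^24) / 2,
             n_bulges = floor((best[sel] %% 2^24) / 2^20),
             n_mismatch = best[sel] %% 2^20)
}

# naive O(n*m) exact-substring degradome mapper, for index equivalence
naive_degradome_map <- function(reads, transcripts) {
  rows <- list()
  for (j in seq_len(nrow(transcripts))) {
    tseq <- transcripts$sequence[j]
    for (k in seq_len(nrow(reads))) {
      rs <- reads$sequence[k]
      w <- nchar(rs)
      if (w > nchar(tseq)) next
      from <- seq_len(nchar(tseq) - w + 1)
      hit <- from[substring(tseq, from, from + w - 1) == rs]  # incl. overlaps
      if (length(hit) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        target_id = transcripts$id[j],
        position = as.integer(hit),
        sequence = rs,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(target_id = character(), position = integer(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df[order(df$target_id, df$position, df$sequence), , drop = FALSE]
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_reads <- function(seqs, counts, label = "test") {
  data.frame(sequence = seqs, raw_count = counts, rpm = 0,
             source_label = label, stringsAsFactors = FALSE)
}
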