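test_that("pair states follow Watson-Crick and wobble rules", {
  expect_equal(pair_state("G", "C"), "WC")
  expect_equal(pair_state("A", "T"), "WC")
  expect_equal(pair_state("G", "T"), "GU")
  expect_equal(pair_state("T", "G"), "GU")
  expect_equal(pair_state("A", "C"), "MM")
  expect_equal(pair_state("A", "G"), "MM")
  expect_equal(pair_state(c("A", "G"), c("T", "T")), c("WC", "GU"))
  expect_error(pair_state("N", "A"), "undetermined")
})

test_that("each scoring rule forces its exact penalty or rejection", {
  wc21 <- rep("WC", 21)

  # perfect duplex scores zero
  expect_equal(score_alignment(wc21)$penalty, 0)
  expect_true(score_alignment(wc21)$accepted)

  # rule: each G:U wobble costs 0.5, anywhere
  s <- wc21; s[5] <- "GU"
  expect_equal(score_alignment(s)$penalty, 0.5)
  s[20] <- "GU"
  expect_equal(score_alignment(s)$penalty, 1.0)

  # rule: seed mismatch costs 1, non-seed mismatch 0.5
  s <- wc21; s[3] <- "MM"
  expect_equal(score_alignment(s)$penalty, 1.0)
  s <- wc21; s[16] <- "MM"
  expect_equal(score_alignment(s)$penalty, 0.5)

  # rule: no mismatch at slicer positions 10/11
  for (p in c(10, 11)) {
    s <- wc21; s[p] <- "MM"
    r <- score_alignment(s)
    expect_false(r$accepted)
    expect_match(r$reason, "forbidden")
  }

  # rule: at most two seed mismatches, G:U not counted
  s <- wc21; s[c(3, 6, 9)] <- "MM"
  expect_match(score_alignment(s)$reason, "seed mismatches")
  s <- wc21; s[c(3, 6)] <- "MM"; s[c(4, 5, 7)] <- "GU"
  r <- score_alignment(s)
  expect_true(r$accepted)          # wobbles don't count toward the cap
  expect_equal(r$penalty, 2 + 1.5)

  # rule: bulge 2.0 plus 0.5 per extra nucleotide, one event per run
  s <- wc21; s[15] <- "GU"
  r <- score_alignment(s, target_bulges = 2L)
  expect_equal(r$penalty, 2.0 + 0.5 + 0.5)
  s <- wc21; s[c(15, 16, 17)] <- "BULGE_SRNA"   # one 3-nt event
  expect_equal(score_alignment(s)$penalty, 2.0 + 1.0)

  # rule: at most two bulge events
  r <- score_alignment(wc21, target_bulges = c(1L, 1L, 1L))
  expect_match(r$reason, "too many bulges")
  s <- wc21; s[5] <- "BULGE_SRNA"; s[15] <- "BULGE_SRNA"
  expect_match(score_alignment(s, target_bulges = 1L)$reason,
               "too many bulges")

  # rule: total penalty capped at 5
  s <- wc21; s[c(3, 6)] <- "MM"; s[c(16, 17)] <- "MM"; s[c(4, 5)] <- "GU"
  r <- score_alignment(s)          # 2 + 1 + 1 = 4
  expect_true(r$accepted)
  expect_equal(r$penalty, 4)
  s[7] <- "GU"; s[8] <- "GU"       # 5, still acceptable
  expect_true(score_alignment(s)$accepted)
  s[9] <- "GU"                     # 5.5
  r <- score_alignment(s)
  expect_false(r$accepted)
  expect_match(r$reason, "max_score")
})

test_that("planted sites are found at exact coordinates and penalties", {
  set.seed(21)
  srna <- random_seq(21)
  site <- revcomp(srna)
  tr <- paste0(random_seq(100), site, random_seq(100))
  hits <- find_candidate_sites(srna, tr)
  top <- hits[1, ]
  expect_equal(top$target_start, 101L)
  expect_equal(top$target_end, 121L)
  expect_equal(top$penalty, 0)
  expect_equal(top$pairmap[[1]], seq(121L, 101L))

  # engineer one non-seed mismatch (position 16 pairs target base 101+5)
  seg <- strsplit(site, "")[[1]]
  seg[21 - 16 + 1] <- substr(srna, 16, 16)   # same base = mismatch
  tr2 <- paste0(substr(tr, 1, 100), paste(seg, collapse = ""),
                substr(tr, 122, nchar(tr)))
  hits2 <- find_candidate_sites(srna, tr2)
  at <- hits2[hits2$target_start == 101L, ]
  expect_equal(at$penalty, 0.5)
  expect_equal(at$target_end, 121L)
})

test_that("scanner equals exhaustive enumeration on random instances", {
  set.seed(1234)
  for (rep in 1:40) {
    srna <- random_seq(sample(18:24, 1))
    tgt <- random_seq(150)
    imp <- find_candidate_sites(srna, tgt)
    imp <- imp[order(imp$target_start),
               c("target_start", "penalty", "n_bulges", "n_mismatch")]
    rownames(imp) <- NULL
    ora <- oracle_scan(srna, tgt)
    expect_equal(imp, ora, info = sprintf("rep %d srna %s", rep, srna))
  }
})

test_that("lowering max_score yields a subset of accepted sites", {
  set.seed(99)
  for (rep in 1:10) {
    srna <- random_seq(21)
    tgt <- random_seq(300)
    h5 <- find_candidate_sites(srna, tgt, scoring_config(max_score = 5))
    h3 <- find_candidate_sites(srna, tgt, scoring_config(max_score = 3))
    expect_true(all(h3$target_start %in% h5$target_start))
    expect_true(all(h3$penalty <= 3 + 1e-9))
    m <- match(h3$target_start, h5$target_start)
    expect_equal(h3$penalty, h5$penalty[m])
  }
})

test_that("gap-free scanning is invariant under sequence reversal with mirrored positions", {
  # reversing both sequences (without complementing, which would break G:U)
  # maps segment [s, e] to [T-e+1, T-s+1] when the position-dependent rules
  # (seed window, forbidden slicer positions) are mirrored too
  set.seed(77)
  for (rep in 1:10) {
    L <- 21
    srna <- random_seq(L)
    tgt <- random_seq(200)
    Tn <- nchar(tgt)
    cfg_f <- scoring_config(max_bulges = 0L)
    cfg_r <- scoring_config(max_bulges = 0L,
                            seed_start = L - 13L + 1L, seed_end = L - 2L + 1L,
                            forbidden_mm_positions = c(L - 9L, L - 10L))
    revstr <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
    fwd <- find_candidate_sites(srna, tgt, cfg_f)
    bwd <- find_candidate_sites(revstr(srna), revstr(tgt), cfg_r)
    mapped <- data.frame(target_start = Tn - bwd$target_end + 1L,
                         penalty = bwd$penalty)
    mapped <- mapped[order(mapped$target_start), ]
    fwd <- fwd[order(fwd$target_start), c("target_start", "penalty")]
    rownames(fwd) <- rownames(mapped) <- NULL
    expect_equal(fwd, mapped)
  }
})

test_that("scanner refuses inadequate queries and skips N windows", {
  expect_error(find_candidate_sites("ACGTACGT", random_seq(100)), "seed")
  expect_error(find_candidate_sites(paste0(random_seq(10), "N",
                                           random_seq(10)),
                                    random_seq(100)), "undetermined")
  srna <- random_seq(21)
  tr <- paste0(substr(revcomp(srna), 1, 10), "N",
               substr(revcomp(srna), 12, 21))
  expect_equal(nrow(find_candidate_sites(srna, tr)), 0L)
})
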