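# build a minimal planted scene: one transcript with a perfect binding site
# for a 21-nt query at a known start, so every coordinate is hand-computable
planted_scene <- function(seed = 41, start_flank = 100) {
  set.seed(seed)
  srna <- random_seq(21)
  tr_seq <- paste0(random_seq(start_flank), revcomp(srna), random_seq(150))
  tr <- data.frame(id = "T1", sequence = tr_seq, stringsAsFactors = FALSE)
  start <- start_flank + 1L
  list(srna = srna, tr = tr, start = start,
       end = start + 20L, cleav = start + 11L)   # pos 10 pairs start + 21 - 10
}

test_that("the expected cleavage window sits opposite sRNA position 10", {
  sc <- planted_scene()
  al <- find_candidate_sites(sc$srna, sc$tr)[1, ]
  expect_equal(al$target_start, sc$start)
  expect_equal(expected_cleavage_window(al, 0L), sc$cleav)
  expect_equal(expected_cleavage_window(al, 1L),
               (sc$cleav - 1L):(sc$cleav + 1L))
  expect_error(expected_cleavage_window(list(pairmap = 1:5)), "fewer than 10")
})

test_that("bulges shift the cleavage window through the base-pair map", {
  set.seed(43)
  srna <- random_seq(21)
  seg <- strsplit(revcomp(srna), "")[[1]]
  # 1-nt target bulge between sRNA positions 5 and 6, i.e. 5' of the slicer
  # position on the sRNA, at higher target coordinates: insert after the
  # base pairing position 6 (segment index 21-6+1 = 16)
  seg2 <- append(seg, "A", after = 16)
  tr <- data.frame(id = "T1",
                   sequence = paste0(random_seq(80), paste(seg2, collapse = ""),
                                     random_seq(80)),
                   stringsAsFactors = FALSE)
  hits <- find_candidate_sites(srna, tr)
  at <- hits[hits$target_start == 81L, ]
  expect_equal(at$penalty, 2.0)
  expect_equal(at$bulges, "T:5:1")
  # explicit base-pair map: 22-nt segment, end = 81+21; pos 1..5 pair
  # end..end-4; the bulged base sits between the partners of 6 and 5,
  # so positions >= 6 pair end-i instead of end-i+1
  pm <- at$pairmap[[1]]
  e <- 81L + 21L
  expect_equal(pm[1:5], e - (1:5) + 1L)
  expect_equal(pm[6:21], e - (6:21))
  expect_equal(expected_cleavage_window(at, 0L), e - 10L)
})

test_that("bait extraction clips the 30-nt window at transcript ends", {
  tr <- data.frame(id = "T1", sequence = random_seq(500),
                   stringsAsFactors = FALSE)
  b <- extract_bait(tr, 100L)
  expect_equal(c(b$window_start, b$window_end), c(85L, 114L))
  expect_equal(nchar(b$sequence), 30L)
  expect_equal(b$sequence, substr(tr$sequence, 85, 114))
  b2 <- extract_bait(tr, 10L)
  expect_equal(c(b2$window_start, b2$window_end), c(1L, 24L))
  expect_equal(nchar(b2$sequence), 24L)
  b3 <- extract_bait(tr, 500L)
  expect_equal(c(b3$window_start, b3$window_end), c(485L, 500L))
  expect_equal(nchar(b3$sequence), 16L)
  expect_error(extract_bait(tr, 501L), "outside")
  expect_error(extract_bait(tr, 0L), "outside")
})

test_that("reverse mining recovers exactly the planted co-regulators", {
  sc <- planted_scene(seed = 43)
  # two variants of the query that still bind the same site: G:U or MM at
  # non-seed positions against the planted (perfectly complementary) site
  v1 <- sc$srna
  substr(v1, 16, 16) <- substr(sc$srna, 16, 16)  # placeholder, build below
  s <- strsplit(sc$srna, "")[[1]]
  tb <- strsplit(revcomp(sc$srna), "")[[1]][21 - 16 + 1]
  alt <- setdiff(c("A", "C", "G", "T"), c(s[16]))
  alt <- alt[pair_state(alt, rep(tb, 3)) != "WC"][1]
  s[16] <- alt
  v1 <- paste(s, collapse = "")
  s2 <- strsplit(sc$srna, "")[[1]]
  tb2 <- strsplit(revcomp(sc$srna), "")[[1]][21 - 18 + 1]
  alt2 <- setdiff(c("A", "C", "G", "T"), s2[18])
  alt2 <- alt2[pair_state(alt2, rep(tb2, 3)) != "WC"][1]
  s2[18] <- alt2
  v2 <- paste(s2, collapse = "")

  set.seed(44)
  decoys <- vapply(1:50, function(i) random_seq(21), character(1))
  reads <- normalize_rpm(make_reads(c(sc$srna, v1, v2, decoys),
                                    c(1000L, 400L, 90L,
                                      sample(1:50, 50, replace = TRUE))))
  bait <- extract_bait(sc$tr, sc$cleav)
  co <- reverse_dig(bait, reads, NULL)
  expect_setequal(co$sequence, c(sc$srna, v1, v2))
  expect_equal(co$sequence[1], sc$srna)          # sorted by rpm descending
  expect_equal(co$retained, c(TRUE, TRUE, FALSE))  # 90 < 1000/10
  expect_equal(co$target_start, rep(sc$start, 3))
  expect_match(co$name, "^sRNA_XX_[123]$")

  # single candidate is always retained
  solo <- normalize_rpm(make_reads(sc$srna, 5L))
  co1 <- reverse_dig(bait, solo, NULL)
  expect_true(co1$retained)

  # known annotation attaches names; novel ids stay stable via registry
  known <- structure(setNames(list("syn-miR1"), sc$srna),
                     class = "known_annotation", species_prefix = "syn-")
  reg <- new_novel_registry("AT")
  co2 <- reverse_dig(bait, reads, known, registry = reg)
  expect_equal(co2$name[1], "syn-miR1")
  expect_true(co2$known[1])
  expect_equal(co2$name[2:3], c("sRNA_AT_1", "sRNA_AT_2"))
  co3 <- reverse_dig(bait, reads, known, registry = reg)
  expect_equal(co2$name, co3$name)
})

test_that("the expression filter keeps rpm >= max/10 and drops the rest", {
  sc <- planted_scene(seed = 45)
  bait <- extract_bait(sc$tr, sc$cleav)
  reads <- normalize_rpm(make_reads(c(sc$srna, random_seq(21)),
                                    c(1000L, 500L)))
  co <- reverse_dig(bait, reads, NULL)
  expect_true(all(co$rpm[co$retained] >= max(co$rpm) / 10))
  expect_true(all(co$rpm[!co$retained] < max(co$rpm) / 10))
  expect_equal(nrow(reverse_dig(bait, reads[0, ], NULL)), 0L)
})

forward_scene <- function(seed = 46, peak = 100L, bg = 5L, displace = 0L,
                          query_count = 1000L, coreg_count = 0L) {
  sc <- planted_scene(seed = seed)
  tr <- sc$tr
  peak_pos <- sc$cleav + displace
  frag <- substr(tr$sequence, peak_pos, peak_pos + 19L)
  bg_pos <- c(10L, 160L, 190L, 220L)
  deg <- make_reads(c(frag, substring(tr$sequence, bg_pos, bg_pos + 19L)),
                    c(peak, rep(bg, 4L)))
  deg <- normalize_rpm(deg)
  srna_seqs <- sc$srna
  counts <- query_count
  if (coreg_count > 0) {
    s <- strsplit(sc$srna, "")[[1]]
    tb <- strsplit(revcomp(sc$srna), "")[[1]][21 - 16 + 1]
    alt <- setdiff(c("A", "C", "G", "T"), s[16])
    s[16] <- alt[pair_state(alt, rep(tb, 3)) != "WC"][1]
    srna_seqs <- c(srna_seqs, paste(s, collapse = ""))
    counts <- c(counts, coreg_count)
  }
  set.seed(seed + 1000)
  decoys <- vapply(1:40, function(i) random_seq(21), character(1))
  sr <- normalize_rpm(make_reads(c(srna_seqs, decoys),
                                 c(counts, sample(1:50, 40, replace = TRUE))))
  list(sc = sc, idx = build_index(deg, tr), sr = sr, tr = tr)
}

test_that("forward mining confirms a planted pair end to end", {
  fs <- forward_scene()
  pairs <- forward_dig(fs$sc$srna, fs$tr, fs$idx, fs$sr)
  expect_length(pairs, 1L)
  p <- pairs[[1]]
  expect_true(p$confirmed)
  expect_equal(p$alignment$target_start, fs$sc$start)
  expect_equal(p$site$position, fs$sc$cleav)
  expect_equal(p$site$ratio, 20)
  expect_true(p$co_regulators$is_query[1])
})

test_that("a peak displaced from the slicer position yields no pair", {
  fs <- forward_scene(displace = 3L)
  pairs <- forward_dig(fs$sc$srna, fs$tr, fs$idx, fs$sr)
  expect_length(pairs, 0L)
  # a tolerant window re-admits it
  pairs3 <- forward_dig(fs$sc$srna, fs$tr, fs$idx, fs$sr, tolerance = 3L)
  expect_length(pairs3, 1L)
})

test_that("an expression-dropped query gives an unconfirmed pair", {
  fs <- forward_scene(query_count = 50L, coreg_count = 1000L)
  pairs <- forward_dig(fs$sc$srna, fs$tr, fs$idx, fs$sr)
  expect_length(pairs, 1L)
  expect_false(pairs[[1]]$confirmed)
  co <- pairs[[1]]$co_regulators
  expect_false(co$retained[co$is_query])
  expect_true(any(co$retained & !co$is_query))
})

test_that("a sub-threshold cleavage ratio gives no pair", {
  fs <- forward_scene(peak = 20L, bg = 5L)   # ratio 4
  expect_length(forward_dig(fs$sc$srna, fs$tr, fs$idx, fs$sr), 0L)
  fs6 <- forward_scene(peak = 30L, bg = 5L)  # ratio 6
  expect_length(forward_dig(fs6$sc$srna, fs6$tr, fs6$idx, fs6$sr), 1L)
})

test_that("queries with undetermined bases are refused", {
  fs <- forward_scene()
  expect_error(forward_dig(paste0("N", substr(fs$sc$srna, 2, 21)),
                           fs$tr, fs$idx, fs$sr), "undetermined")
})

test_that("tissue aggregation confirms on any single passing dataset", {
  fs <- forward_scene()
  good <- forward_dig(fs$sc$srna, fs$tr, fs$idx, fs$sr,
                      source_label = "flower")
  fs_bad <- forward_scene(query_count = 50L, coreg_count = 1000L)
  bad <- forward_dig(fs_bad$sc$srna, fs_bad$tr, fs_bad$idx, fs_bad$sr,
                     source_label = "root")
  agg <- aggregate_tissues(list(flower = good, root = bad))
  expect_length(agg, 1L)
  expect_true(agg[[1]]$confirmed)
  expect_setequal(names(agg[[1]]$evidence), c("flower", "root"))

  agg_none <- aggregate_tissues(list(root = bad))
  expect_false(agg_none[[1]]$confirmed)

  agg_two <- aggregate_tissues(list(flower = good, leaf = good))
  expect_length(agg_two, 1L)
  expect_true(agg_two[[1]]$confirmed)
  expect_length(agg_two[[1]]$evidence, 2L)
})
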