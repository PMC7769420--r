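---
title: "Bidirectional mining of plant sRNA-target pairs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional mining of plant sRNA-target pairs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnadigger)
```

## The problem

Plant miRNAs, ta-siRNAs and siRNAs silence transcripts predominantly by
AGO-mediated cleavage at a site dictated by near-perfect base pairing
between the small RNA and the mRNA. Degradome (PARE) sequencing captures
the uncapped 5' ends of the resulting 3' cleavage fragments, so a genuine
cleavage event leaves a characteristic signal: degradome reads piling up
at one transcript position, the one opposite sRNA position 10.

Conventional degradome pipelines mine in one direction only — known sRNA
to targets. But one site is often cleaved by several sRNAs, many of them
unannotated, and when an unannotated co-regulator is expressed far above
the annotated miRNA, attributing the cleavage to the miRNA alone
misrepresents the regulatory network. This package therefore mines in both
directions:

* **forward** (`forward_dig()`): a query sRNA is scanned against the
  transcriptome for candidate binding sites, each site is validated
  against the degradome, and the call is then *cross-examined in reverse*:
  every expressed sRNA qualified to cleave at that site is recovered, and
  the pair is confirmed only if the query survives among them.
* **reverse** (`reverse_dig()`): starting from a cleavage site, all
  qualifying sRNAs in the sRNA HTS data — annotated or novel — are
  reported as co-regulators, ranked by expression.

## Preprocessing

Collapsed reads (one record per unique sequence, with a count) are
filtered — sequences containing undetermined bases (N) and sequences with
a count of zero are removed, and sRNA reads outside 18–30 nt (the plant
regulatory sRNA range) are dropped; the length window is not applied to
degradome reads, whose length reflects library preparation. Counts are
then normalized to reads per million:

$$\mathrm{RPM} = \frac{\text{raw count}}{\text{total raw count of the dataset}} \times 10^6$$

The denominator is the total over reads that survive filtering, so RPM
sums to $10^6$ in every dataset and expression is comparable across
tissues. Normalizing after filtering is a deliberate choice: the discarded
reads are artifacts, and keeping them in the denominator would make RPM
depend on artifact load.

## Duplex scoring

Candidate binding sites are scored with a position-dependent
complementarity penalty in the psRNATarget family of rules. sRNA positions
are numbered 1..L from the 5' end; the duplex is antiparallel, so position
1 pairs the 3'-most base of the site. With the defaults of
`scoring_config()`:

| rule | penalty |
|---|---|
| G:U wobble | 0.5 each, at any position |
| mismatch, seed (positions 2–13) | 1.0 each, at most 2 (G:U not counted) |
| mismatch, outside the seed | 0.5 each |
| mismatch at position 10 or 11 | rejected outright |
| bulge event (either strand) | 2.0, plus 0.5 per nucleotide beyond the first |
| bulge events | at most 2 |
| total | at most 5.0 |

Positions 10/11 sit at the slicer site, where a mismatch abolishes
cleavage; the asymmetric mismatch cost reads the rule set as a discount
for mismatches *outside* the 2–13 seed (0.5 instead of 1.0). The
alternative convention — doubling the cost inside the seed instead — can
be obtained by setting `mm_penalty_seed`/`mm_penalty_nonseed` directly.
The penalty is computed over the full sRNA length whatever it is, rather
than over a fixed 19-nt window: truncating would silently ignore 3'
pairing that the data contain.

### The alignment grammar, exactly

`find_candidate_sites()` aligns the *entire* sRNA against a contiguous
transcript segment. Bulges must be internal: sRNA positions 1 and L, and
hence both segment boundaries, are paired — a terminal "bulge" would just
be a shorter site with decoration. A run of unpaired nucleotides on one
strand is a single bulge event. Segments containing N are never scored and
never bulged across.

The scanner is a banded dynamic program (C++) over states (sRNA position,
consumed-target offset, gap state, bulge count, seed-mismatch count). The
band half-width is derived from the score budget — with the default
penalties no acceptable alignment can carry more than 7 bulged nucleotides
on one side — so the DP is exhaustive over the grammar, not heuristic. The
test-suite asserts exact equality of accepted sites, penalties, bulge and
mismatch counts against an independent brute-force enumerator on hundreds
of random instances.

One alignment is reported per segment start: the minimum-penalty one, with
ties broken by fewer bulges, then fewer mismatches, then smallest end
coordinate. Every strong site is accompanied in this list by bulged
"shoulder" variants at neighbouring starts; the forward pipeline therefore
keys its results by *cleavage site*, attributing each site to the single
best alignment whose expected cleavage window contains it.

## Degradome validation

Degradome reads are matched to transcripts exactly (no mismatches) and
full-length, each occurrence recorded by its 5'-end position
(`build_index()`, dictionary matching via Biostrings, contractually
identical to naive substring search). For a candidate site at position
$p$ of a transcript:

$$\text{site intensity} = \frac{\sum_{\text{reads at } p} \mathrm{RPM}}{\#\{\text{reads at } p\}},
\qquad
\text{background} = \frac{\sum_{\text{reads not at } p} \mathrm{RPM}}{\#\{\text{reads not at } p\}}$$

where "reads" are distinct collapsed sequences mapped to the *same
transcript* — collapsed datasets make "sequence" synonymous with distinct
species, so both formulas are means per distinct species, and the
background is per transcript because that is what a t-plot displays. A
site is *specific* when site/background $\ge 5$. Two choices deserve
note:

* The background denominator excludes the site's own reads, making
  numerator and denominator range over the same set; the inclusive
  alternative is available as `include_site_reads = TRUE`.
* When the background is exactly zero the ratio is undefined; the site is
  then called specific iff its intensity reaches `min_abs_signal`
  (default 1 RPM), an absolute floor that blocks calls from a single
  spurious read on an otherwise empty transcript.

Intensities use normalized counts, consistent with preprocessing; the
ratio is invariant to that choice within one dataset.

`tplot_data()` exports the per-position summed RPM underlying a t-plot;
column sums conserve the total mapped signal of the transcript.

## The cleavage window and reverse mining

AGO slices between the bases opposite sRNA positions 10 and 11, so the 5'
end of the downstream fragment sits opposite position 10.
`expected_cleavage_window()` reads that position from the alignment's
base-pair map (bulges shift it; the map, not arithmetic on the start
coordinate, is authoritative) and widens it by a configurable `tolerance`
(default 0, i.e. the strict middle of the binding site; ±1 is a
reasonable relaxation since "middle" admits either slicer-flanking base).

For a validated site, `extract_bait()` cuts the 30-nt window centered on
the cleavage position (15 nt upstream, 14 downstream, clipped at
transcript ends). `reverse_dig()` then scans *every* sRNA read against
the bait and keeps those whose duplex passes the scoring rules **and**
whose expected cleavage window covers the bait center — without that
second condition any complementarity anywhere in the 30 nt would qualify,
which is not what co-regulation of one site means. Candidates are ranked
by RPM; those below 1/10 of the strongest candidate are flagged as
dropped, reflecting the observation that cleavage at a shared site is
dominated by the strongly expressed qualifiers. The filter is computed
within one dataset (tissue), because expression — and hence regulatory
status — is tissue-specific. Annotated names are attached by exact
sequence lookup in a species-restricted mature table; unannotated
candidates get stable `sRNA_<tag>_<n>` identifiers in order of first
appearance.

A forward pair is **confirmed** when its query is recovered *and
retained* by this reverse pass. Pairs whose query is expression-dropped
are kept with `confirmed = FALSE` and written to a separate
rejected-pairs report rather than silently discarded — the distinction
between "no evidence" and "outcompeted" is biologically meaningful.
Across tissues, `aggregate_tissues()` confirms a pair overall if any one
dataset confirms it, preserving per-dataset evidence.

Note the order of operations: the expression filter is applied before the
query-recovery check, so a weakly expressed known sRNA at a strongly
co-regulated site is reported as outcompeted, not confirmed.

## The synthetic data generator

`generate_synthetic_data()` builds the study conditions for validation
without downloads: uniform-composition random transcripts (default 12 ×
500 nt); planted binding sites with engineered deviation patterns whose
penalty is known analytically (perfect, one G:U, one non-seed mismatch,
one 1-nt bulge, and substitution-only patterns at exactly 5.0 and 5.5
penalty for the acceptance boundary); degradome datasets with one
dominant 20-nt peak read per planted site (PARE-signature length) at the
expected cleavage position over a uniform background (default 25
fragments per transcript at 1/20 of the peak count); and sRNA datasets
with the planted queries (default count 1000), optional co-regulator
variants, and shuffled random decoys (default 300, counts 1–50). A truth
table states `expected_confirmed` for every pair, computed from the
planted parameters and the thresholds alone.

Design points that keep the truth table analytic:

* Background fragments avoid peak positions and duplicate sequences, so a
  planted site's ratio is exactly `peak_count / background_count`.
* The boundary patterns are substitution-only. A penalty-5.0 pattern built
  from 3'-side bulges can always be undercut by a cheaper gap-free
  alignment sharing the same slicer position (the shifted 3' tail costs at
  most 3.0), so no bulge-based construction can sit *on* the acceptance
  boundary; mismatch/wobble combinations can.
* After embedding, every planted site is verified: the best alignment
  pointing at the planted cleavage position must be the engineered one at
  its engineered penalty (for rejected patterns: no acceptable alignment
  may point there), and no planted sRNA may qualify at another pair's
  site. Violations — accidental cheaper alignments, cross-pair
  complementarity — trigger a deterministic redraw from the same random
  stream, documented here as the generator's collision rule.
* All randomness flows from one master seed through fixed per-dataset
  sub-seeds, so any part regenerates stably and written fixtures are
  byte-identical across runs.

What the generator does *not* emulate: expression gradients and isoform
structure, sequencing error, compositional bias, miRNA families of
near-identical sequences, and the 3'-UTR positional bias of real sites.
Passing on synthetic data therefore demonstrates correctness of the
decision logic at and around every threshold, not recall on real
tissue data.

## Numerical and degenerate-input choices

* Penalty comparisons use a 1e-9 absolute tolerance, generous against
  half-unit penalties and immune to float drift at the 5.0 boundary.
* Tie-breaks are total and deterministic everywhere (alignments: penalty,
  bulges, mismatches, end; co-regulators: RPM, then sequence), so
  identical inputs give byte-identical outputs; novel-id assignment is
  stable given a shared registry.
* Expression-filter comparison is `rpm >= max * 0.1` on normalized
  values; since RPM is proportional to raw counts within a dataset, the
  retained set equals the raw-count computation.
* Empty inputs degrade gracefully: empty query sets or transcripts with
  no mapped reads produce header-only outputs and exit 0; a zero total
  count is an error at normalization, not a NaN downstream.
* sRNAs shorter than the seed end (13 nt) are rejected as queries;
  reads containing N never reach alignment.

## Problem sizes in the tests

The suite validates the scanner against exhaustive enumeration on 200
random instances (18–24-nt sRNAs, 100–250-nt transcripts) and runs the
full pipeline over a 10-pair plan crossing every threshold boundary
(penalty 5.0/5.5, ratio 6/4, displacement 0/3, expression 101/99 against
a 1000-count competitor) for five seeds, plus decoy-safety sweeps. These
sizes keep the whole suite under a few minutes on one CPU while covering
every decision boundary; the properties they assert (oracle equality,
conservation, monotonicity, bidirectional consistency) are
size-independent.

## Known limitations

* sRNAs longer than ~24 nt cannot fit a gap-free duplex inside the 30-nt
  bait, so reverse mining will not recover them even when the forward
  scan finds their site; the bait width is the method's definition, and
  the 18–30 nt preprocessing window intentionally exceeds it.
* Mining is transcriptome-space only; genome mapping, cleavage
  categories (CleaveLand-style 0–4) and site p-values are out of scope.
* Translational repression, target accessibility and duplex free energy
  are not modeled; the score is purely pattern-based.
* Exact-match degradome mapping means SNPs or sequencing errors in
  degradome reads lose signal rather than mis-assigning it.
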