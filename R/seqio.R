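#' @useDynLib srnadigger, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
#' @importFrom utils write.table
"_PACKAGE"

VALID_BASES <- c("A", "C", "G", "T", "N")

normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

check_bases <- function(seqs, ids, what = "record") {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop(sprintf("%s '%s' contains characters outside {A,C,G,T,N}",
                 what, ids[which(bad)[1]]), call. = FALSE)
  }
  invisible(TRUE)
}

first_token <- function(x) sub("\\s.*$", "", x)

#' Read transcript (cDNA) sequences from a FASTA file
#'
#' Sequences are normalized to the DNA alphabet: lowercase is uppercased and
#' U becomes T, so downstream matching of sRNA (RNA-space) against cDNA and
#' degradome (DNA-space) data happens in one alphabet. Coordinates on the
#' returned sequences are 1-based.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` (first whitespace-delimited token
#'   of the header, unique) and `sequence` (over A/C/G/T/N), in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  ids <- first_token(names(ss))
  seqs <- normalize_seq(as.character(ss))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record '", ids[which(!nzchar(seqs))[1]], "'",
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate transcript id '", ids[anyDuplicated(ids)], "' in ", path,
         call. = FALSE)
  }
  check_bases(seqs, ids, "transcript")
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write transcripts to FASTA
#'
#' @param transcripts A data.frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(transcripts, path) {
  ss <- Biostrings::BStringSet(setNames(transcripts$sequence, transcripts$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read abundance-collapsed sequencing reads (sRNA or degradome)
#'
#' Collapsed FASTA carries one record per unique sequence with its read
#' count. Three common count encodings are supported:
#' \describe{
#'   \item{`x_suffix`}{header ends in `_xN` or `_N`, e.g. `>s1_x12`.}
#'   \item{`space_count`}{header is `id N`, count after whitespace.}
#'   \item{`plain`}{raw FASTA; counts obtained by collapsing duplicates.}
#' }
#' Duplicate sequences within one file are collapsed by summing counts in
#' every dialect. RPM is left at 0 until [normalize_rpm()] is applied.
#'
#' @param path Path to the FASTA file.
#' @param dialect Count encoding, one of `"x_suffix"`, `"space_count"`,
#'   `"plain"`.
#' @param source_label Dataset/tissue label attached to every read.
#' @return A data.frame with columns `sequence`, `raw_count`, `rpm`,
#'   `source_label`; sequences unique, in order of first appearance.
#' @export
read_collapsed_reads <- function(path,
                                 dialect = c("x_suffix", "space_count", "plain"),
                                 source_label = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  seqs <- normalize_seq(as.character(ss))
  hdr <- names(ss)
  if (length(ss) == 0) {
    return(data.frame(sequence = character(), raw_count = integer(),
                      rpm = numeric(), source_label = character(),
                      stringsAsFactors = FALSE))
  }
  counts <- switch(dialect,
    x_suffix = {
      tok <- first_token(hdr)
      m <- regmatches(tok, regexpr("_x?([0-9]+)$", tok))
      if (any(lengths(regmatches(tok, gregexpr("_x?[0-9]+$", tok))) == 0)) {
        bad <- which(!grepl("_x?[0-9]+$", tok))[1]
        stop(sprintf("record %d ('%s'): cannot parse count from x_suffix header",
                     bad, tok[bad]), call. = FALSE)
      }
      as.integer(sub("^_x?", "", m))
    },
    space_count = {
      cnt <- sub("^\\S+\\s+", "", hdr)
      ok <- grepl("^\\S+\\s+[0-9]+\\s*$", hdr)
      if (!all(ok)) {
        bad <- which(!ok)[1]
        stop(sprintf("record %d ('%s'): cannot parse count from space_count header",
                     bad, hdr[bad]), call. = FALSE)
      }
      as.integer(cnt)
    },
    plain = rep.int(1L, length(ss))
  )
  check_bases(seqs, first_token(hdr), "read")
  agg <- rowsum(as.numeric(counts), group = seqs, reorder = FALSE)
  data.frame(sequence = rownames(agg),
             raw_count = as.integer(agg[, 1]),
             rpm = 0,
             source_label = source_label,
             stringsAsFactors = FALSE)
}

#' Write abundance-collapsed reads to FASTA
#'
#' Inverse of [read_collapsed_reads()] for each dialect. In the `plain`
#' dialect each sequence is written `raw_count` times.
#'
#' @param reads A reads data.frame (`sequence`, `raw_count`, ...).
#' @param path Output path.
#' @param dialect Count encoding (see [read_collapsed_reads()]).
#' @param id_prefix Prefix for generated record ids.
#' @return Invisibly, `path`.
#' @export
write_collapsed_reads <- function(reads, path,
                                  dialect = c("x_suffix", "space_count", "plain"),
                                  id_prefix = "s") {
  dialect <- match.arg(dialect)
  n <- nrow(reads)
  lines <- switch(dialect,
    x_suffix = rbind(sprintf(">%s%d_x%d", id_prefix, seq_len(n), reads$raw_count),
                     reads$sequence),
    space_count = rbind(sprintf(">%s%d %d", id_prefix, seq_len(n), reads$raw_count),
                        reads$sequence),
    plain = {
      rep_seq <- rep(reads$sequence, times = reads$raw_count)
      rbind(sprintf(">%s%d", id_prefix, seq_along(rep_seq)), rep_seq)
    })
  writeLines(as.vector(lines), path)
  invisible(path)
}

#' Read miRBase-style mature sRNA annotations
#'
#' Builds an exact-sequence lookup from mature sequences (RNA alphabet in
#' miRBase; normalized to DNA here) to annotated names, restricted to one
#' species by its name prefix (e.g. `"ath-"` for Arabidopsis thaliana).
#' A sequence carried by several mature entries keeps all its names. A
#' sequence absent from the table is "novel"/unannotated.
#'
#' @param path Path to a mature FASTA file (headers like `ath-miR156a-5p`).
#' @param species_prefix Keep only records whose name starts with this.
#' @return An object of class `known_annotation`: a named list mapping
#'   sequence to a character vector of names.
#' @export
read_known_annotations <- function(path, species_prefix) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  nm <- first_token(names(ss))
  keep <- startsWith(nm, species_prefix)
  if (!any(keep)) {
    warning("no mature records match species prefix '", species_prefix,
            "'; all sRNAs will be reported as novel", call. = FALSE)
  }
  nm <- nm[keep]
  seqs <- normalize_seq(as.character(ss)[keep])
  map <- split(nm, seqs)[unique(seqs)]
  structure(as.list(map), class = "known_annotation",
            species_prefix = species_prefix)
}

#' Look up annotated names for sRNA sequences
#'
#' @param known A `known_annotation` object (may be `NULL` for novel-only
#'   mode).
#' @param sequences Character vector of sequences (DNA alphabet).
#' @return A list, one character vector of names per sequence (empty vector
#'   = unannotated).
#' @export
lookup_known <- function(known, sequences) {
  if (is.null(known)) return(rep(list(character()), length(sequences)))
  out <- unclass(known)[sequences]
  out[vapply(out, is.null, logical(1))] <- list(character())
  names(out) <- sequences
  out
}

#' @export
print.known_annotation <- function(x, ...) {
  cat(sprintf("known_annotation: %d sequences, %d names (prefix '%s')\n",
              length(x), length(unlist(x)), attr(x, "species_prefix")))
  invisible(x)
}

#' Flatten target pairs to one row per co-regulator
#'
#' @param pairs A list of `target_pair` objects (see [forward_dig()]).
#' @return A data.frame with one row per (sRNA, target, site, co-regulator),
#'   ordered by transcript id ascending, then co-regulator RPM descending,
#'   ties by sequence.
#' @export
as_pair_rows <- function(pairs) {
  cols <- c("transcript_id", "site_position", "srna_name_or_novel_id",
            "srna_sequence", "raw_count", "rpm", "penalty_score",
            "alignment_string", "site_intensity", "background_intensity",
            "ratio", "retained_flag", "source_label")
  if (length(pairs) == 0) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
    return(df)
  }
  blocks <- lapply(pairs, function(p) {
    co <- p$co_regulators
    data.frame(
      transcript_id = p$target_id,
      site_position = p$site$position,
      srna_name_or_novel_id = co$name,
      srna_sequence = co$sequence,
      raw_count = co$raw_count,
      rpm = co$rpm,
      penalty_score = co$penalty,
      alignment_string = co$states,
      site_intensity = p$site$site_intensity,
      background_intensity = p$site$background_intensity,
      ratio = p$site$ratio,
      retained_flag = co$retained,
      source_label = p$source_label,
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, blocks)
  df <- df[order(df$transcript_id, -df$rpm, df$srna_sequence), , drop = FALSE]
  rownames(df) <- NULL
  df[, cols]
}

#' Write target pairs as a tab-delimited table
#'
#' One row per (sRNA, target, site, co-regulator); rows ordered by
#' transcript id ascending, then sRNA RPM descending, ties by sequence.
#'
#' @param pairs A list of `target_pair` objects, or an already-flattened
#'   data.frame from [as_pair_rows()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pairs_tsv <- function(pairs, path) {
  df <- if (is.data.frame(pairs)) pairs else as_pair_rows(pairs)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
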