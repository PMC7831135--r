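#' @include align.R
NULL

# Karlin-Altschul E-values. Protein: gapped BLOSUM62 lambda/K; nucleotide:
# exact ungapped solution for +1/-1 at uniform composition (lambda = ln 3).
# E = K * m * n * exp(-lambda * S) with n = total scaffold length * 2 strands.
.ka_params <- function(type) {
  if (type == "aa") c(lambda = 0.267, K = 0.041) else c(lambda = log(3), K = 0.333)
}

.evalue <- function(score, qlen, dblen, type) {
  p <- .ka_params(type)
  unname(p["K"] * qlen * dblen * exp(-p["lambda"] * score))
}

.hit_row <- function(query_id, scaffold_id, start, end, strand, frame,
                     score, evalue, identity) {
  data.frame(query = query_id, scaffold = scaffold_id,
             start = as.integer(start), end = as.integer(end),
             strand = strand, frame = as.integer(frame),
             score = as.numeric(score), evalue = as.numeric(evalue),
             identity = as.numeric(identity), stringsAsFactors = FALSE)
}

# pick the best hit under the documented tie-break:
# higher score, lower evalue, lexicographic scaffold id, smaller start
.best_hit <- function(hits) {
  if (!nrow(hits)) return(NULL)
  ord <- order(-hits$score, hits$evalue, hits$scaffold, hits$start)
  hits[ord[[1L]], , drop = FALSE]
}

#' Translated homology search (TBLASTN-style surrogate)
#'
#' Searches a protein query against all six reading frames of every
#' scaffold of a genome by exact amino-acid 5-mer seeding and local
#' alignment extension, and returns the single best hit passing the
#' E-value cutoff. Hit coordinates are 0-based half-open nucleotide
#' coordinates on the forward strand of the named scaffold.
#'
#' @param query named character of length 1, or an `AAStringSet` of length
#'   1: the protein query.
#' @param genome a [GenomeAssembly-class].
#' @param evalue_cutoff maximum E-value (default `1e-10`).
#' @param word seed word size (default 5).
#' @param frames_cache optional precomputed six-frame translations (named
#'   list scaffold -> [sixFrameTranslate()] output) to avoid re-translating
#'   the genome for every query; see [genomeFrames()].
#' @return one-row data.frame (query, scaffold, start, end, strand, frame,
#'   score, evalue, identity) or `NULL` if no hit passes the cutoff.
#' @export
translatedSearch <- function(query, genome, evalue_cutoff = 1e-10, word = 5L,
                             frames_cache = NULL) {
  qid <- names(query)[[1L]]
  if (is.null(qid)) qid <- "query"
  qseq <- toupper(as.character(query)[[1L]])
  scafs <- scaffolds(genome)
  dblen <- 2 * sum(Biostrings::width(scafs))
  rows <- list()
  for (sid in sort(names(scafs))) {
    s <- as.character(scafs[[sid]])
    slen <- nchar(s)
    if (slen < 3L) next
    frames <- if (!is.null(frames_cache)) frames_cache[[sid]]
              else sixFrameTranslate(s)
    for (fr in names(frames)) {
      subj <- frames[[fr]]
      if (nchar(subj) < word) next
      r <- .cpp_seeded_local(qseq, subj, as.integer(word), "aa")
      if (as.numeric(r[["score"]]) <= 0) next
      ev <- .evalue(as.numeric(r[["score"]]), nchar(qseq), dblen, "aa")
      if (ev > evalue_cutoff) next
      off <- abs(as.integer(substr(fr, 2L, 2L))) - 1L # 0,1,2
      aa_s <- r[["b_start"]]; aa_e <- r[["b_end"]]
      if (substr(fr, 1L, 1L) == "+") {
        nt_s <- off + 3L * aa_s
        nt_e <- off + 3L * aa_e
        strand <- "+"
      } else {
        # frame on reverse complement: rc position p <-> forward slen-1-p
        nt_e <- slen - (off + 3L * aa_s)
        nt_s <- slen - (off + 3L * aa_e)
        strand <- "-"
      }
      rows[[length(rows) + 1L]] <- .hit_row(
        qid, sid, nt_s, nt_e, strand, abs(as.integer(substr(fr, 2L, 2L))),
        r[["score"]], ev, r[["identity"]])
    }
  }
  if (!length(rows)) return(NULL)
  .best_hit(do.call(rbind, rows))
}

#' Nucleotide homology search (BLASTN-style surrogate)
#'
#' As [translatedSearch()] but with nucleotide seeding (word size 11)
#' against both strands of every scaffold.
#'
#' @param query named character of length 1 (or `DNAStringSet` of length 1).
#' @inheritParams translatedSearch
#' @param word seed word size (default 11).
#' @return one-row data.frame as [translatedSearch()] (frame is `NA`), or
#'   `NULL`.
#' @export
nucleotideSearch <- function(query, genome, evalue_cutoff = 1e-10, word = 11L) {
  qid <- names(query)[[1L]]
  if (is.null(qid)) qid <- "query"
  qseq <- toupper(as.character(query)[[1L]])
  scafs <- scaffolds(genome)
  dblen <- 2 * sum(Biostrings::width(scafs))
  rows <- list()
  for (sid in sort(names(scafs))) {
    s <- as.character(scafs[[sid]])
    slen <- nchar(s)
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") s else revComp(s)
      if (nchar(subj) < word) next
      r <- .cpp_seeded_local(qseq, subj, as.integer(word), "nt")
      if (as.numeric(r[["score"]]) <= 0) next
      ev <- .evalue(as.numeric(r[["score"]]), nchar(qseq), dblen, "nt")
      if (ev > evalue_cutoff) next
      if (strand == "+") {
        nt_s <- r[["b_start"]]; nt_e <- r[["b_end"]]
      } else {
        nt_s <- slen - r[["b_end"]]; nt_e <- slen - r[["b_start"]]
      }
      rows[[length(rows) + 1L]] <- .hit_row(
        qid, sid, nt_s, nt_e, strand, NA_integer_,
        r[["score"]], ev, r[["identity"]])
    }
  }
  if (!length(rows)) return(NULL)
  .best_hit(do.call(rbind, rows))
}

#' Precompute six-frame translations of every scaffold
#'
#' Useful when many protein queries are searched against the same genome:
#' pass the result as `frames_cache` to [translatedSearch()].
#'
#' @param genome a [GenomeAssembly-class].
#' @return named list, scaffold -> six-frame translation vector.
#' @export
genomeFrames <- function(genome) {
  scafs <- scaffolds(genome)
  out <- list()
  for (sid in names(scafs)) {
    s <- as.character(scafs[[sid]])
    if (nchar(s) >= 3L) out[[sid]] <- sixFrameTranslate(s)
  }
  out
}

#' Extend a hit to the expected gene length
#'
#' Extends a search hit symmetrically at each end to reach the expected
#' nucleotide length, truncating at scaffold ends (a truncation deficit at
#' one end is not compensated at the other). The returned sequence is
#' strand-corrected: reverse-complemented for minus-strand hits.
#'
#' @param hit a one-row hit data.frame from [translatedSearch()] or
#'   [nucleotideSearch()].
#' @param expected_len_nt expected full gene length in nucleotides.
#' @param genome the [GenomeAssembly-class] the hit refers to.
#' @return nucleotide string of length `<= expected_len_nt`.
#' @export
extendHit <- function(hit, expected_len_nt, genome) {
  scafs <- scaffolds(genome)
  s <- as.character(scafs[[hit$scaffold]])
  slen <- nchar(s)
  span <- hit$end - hit$start
  if (expected_len_nt < span) {
    warning("expected length ", expected_len_nt, " shorter than hit span ", span,
            "; returning the hit span unextended")
    lo <- hit$start; hi <- hit$end
  } else {
    extra <- expected_len_nt - span
    left <- extra %/% 2L
    right <- extra - left
    if (hit$strand == "-") { tmp <- left; left <- right; right <- tmp }
    lo <- max(0L, hit$start - left)
    hi <- min(slen, hit$end + right)
  }
  out <- substr(s, lo + 1L, hi)
  if (hit$strand == "-") out <- revComp(out)
  out
}

#' Write search hits as TSV
#'
#' Coordinates are reported 1-based closed (internal coordinates are
#' 0-based half-open).
#'
#' @param hits data.frame of hit rows.
#' @param path output path.
#' @export
writeHits <- function(hits, path) {
  out <- data.frame(query = hits$query, scaffold = hits$scaffold,
                    start1 = hits$start + 1L, end1 = hits$end,
                    strand = hits$strand, frame = hits$frame,
                    identity = hits$identity, score = hits$score,
                    evalue = hits$evalue)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
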