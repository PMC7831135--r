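#' @include seqio.R
NULL

# Scoring used throughout: nucleotide match +1 / mismatch -1, gap open 5,
# gap extend 2 (a gap of length L costs open + L*extend); protein BLOSUM62
# with gap open 11 / extend 1. Ambiguity codes are mismatches and never seed.

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' @param a,b sequences (character strings).
#' @param type `"nt"` or `"aa"` (selects the scoring scheme above).
#' @return list with `score`, `identity` (matching fraction of aligned
#'   columns), gapped `a_aln`/`b_aln` strings, and 0-based half-open
#'   coordinates `a_start`/`a_end`/`b_start`/`b_end` of the aligned region.
#'   Traceback ties are broken diagonal > up > left, so results are
#'   deterministic.
#' @examples
#' localAlign("ACGT", "ACGT")$score  # 4
#' @export
localAlign <- function(a, b, type = c("nt", "aa")) {
  type <- match.arg(type)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  .cpp_local_align(toupper(a), toupper(b), type)
}

#' Optimal global alignment (Needleman-Wunsch, affine gaps)
#'
#' @inheritParams localAlign
#' @param free_end_b free end gaps on `b` (semi-global: `a` is aligned
#'   end-to-end inside `b`).
#' @return as [localAlign()].
#' @export
globalAlign <- function(a, b, type = c("nt", "aa"), free_end_b = FALSE) {
  type <- match.arg(type)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  .cpp_global_align(toupper(a), toupper(b), type, free_end_b)
}

#' Banded global identity between two long sequences
#'
#' Global alignment restricted to a diagonal band; used as the whole-genome
#' alignment oracle for fragment ANI on small genomes.
#'
#' @inheritParams localAlign
#' @param band half-width of the diagonal band.
#' @return list with `score`, `identity`, `matches`, `columns`.
#' @export
bandedGlobalAlign <- function(a, b, band = 200L, type = c("nt", "aa")) {
  type <- match.arg(type)
  .cpp_banded_align(toupper(a), toupper(b), as.integer(band), type,
                    FALSE, 0L)
}
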