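#' @include simulate.R
NULL

#' ANI parameters
#'
#' Fragment-based ANI parameterization: 16-mer seeding, 3000-nt fragments,
#' and a minimum shared fragment fraction of 0.2 below which ANI is
#' reported as undefined.
#'
#' @param kmer seed k-mer size (>= 8).
#' @param fragment_len fragment length in nt (>= 10 * kmer).
#' @param min_shared_fraction minimum fragments_mapped/fragments_total for
#'   ANI to be defined, in (0, 1].
#' @param band half-width of the banded alignment used per fragment.
#' @param min_seeds minimum shared seed k-mers for a reference window to be
#'   accepted.
#' @param min_map_identity minimum alignment identity for a fragment to
#'   count as mapped (default 0.8, mirroring the Mashmap mapping-identity
#'   floor used by fragment-ANI tools); lower-identity fragments are
#'   treated as unmapped.
#' @return list of class `aniParams`.
#' @export
aniParams <- function(kmer = 16L, fragment_len = 3000L,
                      min_shared_fraction = 0.2, band = 32L, min_seeds = 5L,
                      min_map_identity = 0.8) {
  p <- list(kmer = as.integer(kmer), fragment_len = as.integer(fragment_len),
            min_shared_fraction = as.numeric(min_shared_fraction),
            band = as.integer(band), min_seeds = as.integer(min_seeds),
            min_map_identity = as.numeric(min_map_identity))
  stopifnot(p$kmer >= 8L, p$fragment_len >= 10L * p$kmer,
            p$min_shared_fraction > 0, p$min_shared_fraction <= 1)
  class(p) <- "aniParams"
  p
}

#' Cut a genome into non-overlapping fragments
#'
#' Each scaffold is cut into consecutive non-overlapping windows of
#' `fragment_len`; a terminal remainder shorter than `fragment_len` is
#' discarded. Fragments carry their origin coordinates.
#'
#' @param genome a [GenomeAssembly-class].
#' @param fragment_len window size in nt.
#' @return data.frame with columns scaffold, start, end (0-based half-open)
#'   and seq.
#' @export
fragmentGenome <- function(genome, fragment_len = 3000L) {
  scafs <- scaffolds(genome)
  out <- list()
  for (sid in names(scafs)) {
    s <- as.character(scafs[[sid]])
    nfrag <- nchar(s) %/% fragment_len
    if (nfrag == 0L) next
    starts <- (seq_len(nfrag) - 1L) * fragment_len
    out[[sid]] <- data.frame(
      scaffold = sid, start = starts, end = starts + fragment_len,
      seq = substring(s, starts + 1L, starts + fragment_len),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), seq = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# reference scaffolds plus reverse complements, as the C++ mapper expects
.ref_subjects <- function(genome) {
  scafs <- as.character(scaffolds(genome))
  c(scafs, vapply(scafs, revComp, ""))
}

#' Map one fragment against a reference genome
#'
#' Seeds by shared k-mers against both strands of the reference, selects
#' the window with the most shared seeds, and computes identity over a
#' banded alignment of the fragment against that window. Returns `NA` when
#' no window reaches `min_seeds` shared k-mers.
#'
#' @param fragment nucleotide string (one row of [fragmentGenome()]).
#' @param reference a [GenomeAssembly-class].
#' @param params an [aniParams()] object.
#' @return identity percent in `[0, 100]`, or `NA`.
#' @export
mapFragment <- function(fragment, reference, params = aniParams()) {
  r <- .cpp_fragment_map(fragment, .ref_subjects(reference),
                         params$kmer, params$band, params$min_seeds)
  id <- r$identity[[1L]]
  if (!is.na(id) && id < params$min_map_identity) id <- NA_real_
  100 * id
}

#' Directed fragment ANI between two assemblies
#'
#' Fragments of the query are mapped against the reference; ANI is the
#' mean identity of mapped fragments, and is undefined (`NA`) when fewer
#' than `min_shared_fraction` of the fragments map.
#'
#' @param query,reference [GenomeAssembly-class] objects.
#' @param params an [aniParams()] object.
#' @return one-row data.frame: query, reference, ani (percent or `NA`),
#'   fragments_total, fragments_mapped, shared_fraction.
#' @export
aniPair <- function(query, reference, params = aniParams()) {
  fr <- fragmentGenome(query, params$fragment_len)
  total <- nrow(fr)
  if (total == 0L)
    return(data.frame(query = strainId(query), reference = strainId(reference),
                      ani = NA_real_, fragments_total = 0L,
                      fragments_mapped = 0L, shared_fraction = NA_real_))
  r <- .cpp_fragment_map(fr$seq, .ref_subjects(reference),
                         params$kmer, params$band, params$min_seeds)
  ident <- r$identity
  ident[!is.na(ident) & ident < params$min_map_identity] <- NA_real_
  mapped <- sum(!is.na(ident))
  shared <- mapped / total
  ani <- if (shared >= params$min_shared_fraction && mapped > 0)
    100 * mean(ident, na.rm = TRUE) else NA_real_
  data.frame(query = strainId(query), reference = strainId(reference),
             ani = ani, fragments_total = total, fragments_mapped = mapped,
             shared_fraction = shared, stringsAsFactors = FALSE)
}

#' Symmetrized pairwise ANI matrix
#'
#' Computes both directions for each pair; the symmetrized value is the
#' mean of the two defined directions (or the single defined one, `NA` if
#' both are undefined). The diagonal is 100.
#'
#' @param genomes named list of [GenomeAssembly-class] objects.
#' @param params an [aniParams()] object.
#' @return list with `matrix` (symmetric, `NA` for undefined) and
#'   `records` (long-form directed data.frame).
#' @export
aniMatrix <- function(genomes, params = aniParams()) {
  ids <- vapply(genomes, strainId, "")
  n <- length(ids)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 100
  recs <- list()
  frags <- lapply(genomes, function(g) fragmentGenome(g, params$fragment_len))
  for (j in seq_len(n)) { # reference-major: one index build per reference
    qidx <- setdiff(seq_len(n), j)
    qidx <- qidx[vapply(qidx, function(i) nrow(frags[[i]]) > 0L, TRUE)]
    if (!length(qidx)) next
    batch <- unlist(lapply(qidx, function(i) frags[[i]]$seq), use.names = FALSE)
    origin <- rep(qidx, vapply(qidx, function(i) nrow(frags[[i]]), 0L))
    r <- .cpp_fragment_map(batch, .ref_subjects(genomes[[j]]),
                           params$kmer, params$band, params$min_seeds)
    for (i in qidx) {
      ident <- r$identity[origin == i]
      ident[!is.na(ident) & ident < params$min_map_identity] <- NA_real_
      total <- length(ident)
      mapped <- sum(!is.na(ident))
      shared <- mapped / total
      ani <- if (shared >= params$min_shared_fraction && mapped > 0)
        100 * mean(ident, na.rm = TRUE) else NA_real_
      recs[[paste(ids[[i]], ids[[j]])]] <- data.frame(
        query = ids[[i]], reference = ids[[j]], ani = ani,
        fragments_total = total, fragments_mapped = mapped,
        shared_fraction = shared, stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, recs)
  rownames(rec) <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    a <- rec$ani[rec$query == ids[[i]] & rec$reference == ids[[j]]]
    b <- rec$ani[rec$query == ids[[j]] & rec$reference == ids[[i]]]
    vals <- c(a, b)
    vals <- vals[!is.na(vals)]
    m[i, j] <- m[j, i] <- if (length(vals)) mean(vals) else NA_real_
  }
  list(matrix = m, records = rec)
}

#' Write an ANI matrix and its long form as TSV
#'
#' @param ani result of [aniMatrix()].
#' @param matrix_path,long_path output paths (either may be `NULL`).
#' @export
writeAniMatrix <- function(ani, matrix_path = NULL, long_path = NULL) {
  if (!is.null(matrix_path)) {
    df <- data.frame(strain = rownames(ani$matrix), ani$matrix,
                     check.names = FALSE)
    write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
  }
  if (!is.null(long_path))
    write.table(ani$records, long_path, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
  invisible(NULL)
}
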