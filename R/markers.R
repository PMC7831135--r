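#' @include accessory.R
NULL

#' Extract the 16S rRNA gene from an assembly
#'
#' Best nucleotide-search hit of the reference 16S, extended to the
#' reference length. Returns `NULL` when the genome has no hit; hits
#' shorter than 90% of the reference length are flagged incomplete (and
#' should be excluded from haplotyping).
#'
#' @param genome a [GenomeAssembly-class].
#' @param reference_16s reference 16S sequence (character).
#' @param evalue E-value cutoff.
#' @return list with `seq` and `incomplete`, or `NULL`.
#' @export
extract16S <- function(genome, reference_16s, evalue = 1e-10) {
  hit <- nucleotideSearch(c(rrs = reference_16s), genome, evalue_cutoff = evalue)
  if (is.null(hit)) return(NULL)
  seq <- extendHit(hit, nchar(reference_16s), genome)
  list(seq = seq, incomplete = nchar(seq) < 0.9 * nchar(reference_16s))
}

#' Profile a 16S sequence against the standard sequence
#'
#' Global alignment to the standard; substitutions and insertions are
#' reported in 1-based standard coordinates. Deletions relative to the
#' standard are reported as substitutions to `"-"`, so that applying the
#' reported variants to the standard reconstructs the observed sequence
#' exactly. An insertion of length >= 20 anchored at standard positions
#' 72-77 (replacing the 4-base loop at 73-76) is additionally flagged as
#' an intervening sequence (IVS).
#'
#' @param sequence observed 16S sequence.
#' @param standard_16s the standard 16S sequence.
#' @return list of class `sixteenSProfile`: `substitutions` (data.frame
#'   position, standard, observed), `insertions` (data.frame position =
#'   standard position after which the insert occurs, length, sequence),
#'   `ivs` (logical), `ivs_length`.
#' @export
profile16S <- function(sequence, standard_16s) {
  r <- globalAlign(sequence, standard_16s, type = "nt")
  a <- strsplit(r$a_aln, "")[[1L]] # observed
  b <- strsplit(r$b_aln, "")[[1L]] # standard
  refpos <- cumsum(b != "-")
  subs <- data.frame(position = integer(), standard = character(),
                     observed = character(), stringsAsFactors = FALSE)
  ins <- data.frame(position = integer(), length = integer(),
                    sequence = character(), stringsAsFactors = FALSE)
  i <- 1L
  while (i <= length(a)) {
    if (b[[i]] == "-") { # insertion run
      j <- i
      while (j < length(a) && b[[j + 1L]] == "-") j <- j + 1L
      ins <- rbind(ins, data.frame(
        position = if (i == 1L) 0L else refpos[[i - 1L]],
        length = j - i + 1L,
        sequence = paste0(a[i:j], collapse = ""), stringsAsFactors = FALSE))
      i <- j + 1L
    } else {
      if (a[[i]] != b[[i]]) {
        obs <- if (a[[i]] == "-") "-" else a[[i]]
        subs <- rbind(subs, data.frame(position = refpos[[i]],
                                       standard = b[[i]], observed = obs,
                                       stringsAsFactors = FALSE))
      }
      i <- i + 1L
    }
  }
  # IVS: the observed bases spanning the loop region (strictly between the
  # columns aligned to standard positions 72 and 77); >= 20 observed bases
  # there means the 4-base loop was replaced by an intervening sequence.
  # Counting between fixed anchors is robust to how the aligner distributes
  # the insert across insertion runs and loop columns.
  ivs <- FALSE; ivs_len <- NA_integer_
  col72 <- which(b != "-" & refpos == 72L)
  col77 <- which(b != "-" & refpos == 77L)
  if (length(col72) == 1L && length(col77) == 1L && col77 > col72 + 1L) {
    span <- a[(col72 + 1L):(col77 - 1L)]
    n_obs <- sum(span != "-")
    if (n_obs >= 20L) { ivs <- TRUE; ivs_len <- n_obs }
  }
  structure(list(substitutions = subs, insertions = ins,
                 ivs = ivs, ivs_length = ivs_len),
            class = "sixteenSProfile")
}

#' Reconstruct the observed sequence from a profile
#'
#' Applies a [profile16S()] variant list to the standard sequence;
#' the round trip is exact.
#'
#' @param profile a `sixteenSProfile`.
#' @param standard_16s the standard sequence.
#' @return the reconstructed observed sequence.
#' @export
applyProfile16S <- function(profile, standard_16s) {
  chars <- strsplit(standard_16s, "")[[1L]]
  for (k in seq_len(nrow(profile$substitutions))) {
    p <- profile$substitutions$position[[k]]
    chars[[p]] <- profile$substitutions$observed[[k]]
  }
  inserts <- setNames(rep("", length(chars) + 1L), 0:length(chars))
  for (k in seq_len(nrow(profile$insertions)))
    inserts[[as.character(profile$insertions$position[[k]])]] <-
      profile$insertions$sequence[[k]]
  out <- inserts[["0"]]
  for (i in seq_along(chars)) {
    ch <- chars[[i]]
    if (ch != "-") out <- paste0(out, ch)
    out <- paste0(out, inserts[[as.character(i)]])
  }
  out
}

# canonical key of a profile after optional masking
.profile_key <- function(subs, ins) {
  paste(
    paste(sprintf("s%d%s>%s", subs$position, subs$standard, subs$observed),
          collapse = ";"),
    paste(sprintf("i%d+%s", ins$position, ins$sequence), collapse = ";"),
    sep = "|")
}

#' Catalog 16S haplotypes across strains
#'
#' Substitution variants observed in exactly one strain are masked before
#' haplotype assignment (single-strain insertions are kept); the distinct
#' remaining profiles are enumerated with their member strains.
#'
#' @param profiles named list of `sixteenSProfile` objects (strain ->
#'   profile).
#' @return data.frame with columns strain, haplotype.
#' @export
catalogHaplotypes <- function(profiles) {
  # count strains carrying each substitution variant
  all_subs <- list()
  for (s in names(profiles)) {
    su <- profiles[[s]]$substitutions
    if (nrow(su))
      all_subs[[s]] <- sprintf("%d%s>%s", su$position, su$standard, su$observed)
  }
  tab <- table(unlist(all_subs))
  private <- names(tab)[tab == 1L]
  keys <- vapply(names(profiles), function(s) {
    su <- profiles[[s]]$substitutions
    if (nrow(su)) {
      v <- sprintf("%d%s>%s", su$position, su$standard, su$observed)
      su <- su[!(v %in% private), , drop = FALSE]
    }
    .profile_key(su, profiles[[s]]$insertions)
  }, "")
  hap_ids <- setNames(sprintf("H%02d", seq_along(unique(keys))), unique(keys))
  data.frame(strain = names(profiles), haplotype = unname(hap_ids[keys]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign a symbiovar from nodulation genes
#'
#' For each of NodD/NodA/NodB/NodC, the three symbiovar reference alleles
#' are searched against the genome (translated search); the per-gene vote
#' is the symbiovar of the best-scoring reference. The call is the
#' unanimous vote over present genes when at least two genes are present;
#' a genome with only NodA (or nothing) is non-nodulating; non-unanimous
#' votes yield `"conflict"`.
#'
#' @param genome a [GenomeAssembly-class].
#' @param nod_references named character vector of reference proteins,
#'   names `<gene>_<symbiovar>` (e.g. `nodA_viciae`).
#' @param evalue E-value cutoff (default `1e-5`).
#' @return list of class `symbiovarCall`: `strain`, `call`, `genes`
#'   (named character per gene: best symbiovar or `NA`).
#' @export
assignSymbiovar <- function(genome, nod_references, evalue = 1e-5) {
  genes <- c("nodD", "nodA", "nodB", "nodC")
  frames <- genomeFrames(genome)
  votes <- setNames(rep(NA_character_, 4L), genes)
  for (g in genes) {
    refs <- nod_references[grep(paste0("^", g, "_"), names(nod_references))]
    if (!length(refs)) next
    best_sv <- NA_character_; best_score <- -Inf
    for (nm in sort(names(refs))) {
      hit <- translatedSearch(setNames(refs[[nm]], nm), genome,
                              evalue_cutoff = evalue, frames_cache = frames)
      if (is.null(hit)) next
      if (hit$score > best_score) {
        best_score <- hit$score
        best_sv <- sub(paste0("^", g, "_"), "", nm)
      }
    }
    votes[[g]] <- best_sv
  }
  present <- votes[!is.na(votes)]
  present_non_a <- present[names(present) != "nodA"]
  call <- if (length(present) == 0L ||
              (length(present) == 1L && names(present) == "nodA")) {
    "nonnodulating"
  } else if (length(present) < 2L) {
    "nonnodulating"
  } else if (length(unique(present)) == 1L) {
    unname(present[[1L]])
  } else "conflict"
  structure(list(strain = strainId(genome), call = call, genes = votes),
            class = "symbiovarCall")
}

#' Primer pair definition
#'
#' @param gene gene name.
#' @param forward,reverse primer sequences (reverse given 5'->3' on the
#'   opposite strand, as usual).
#' @param informative_len expected informative (interior) length in nt.
#' @return list of class `primerPair`.
#' @export
primerPair <- function(gene, forward, reverse, informative_len) {
  stopifnot(nzchar(forward), nzchar(reverse), informative_len > 0)
  structure(list(gene = gene, forward = toupper(forward),
                 reverse = toupper(reverse),
                 informative_len = as.integer(informative_len)),
            class = "primerPair")
}

# best match of a primer in seq with <= max_mm mismatches; returns 0-based
# half-open span or NULL
.find_primer <- function(seq, primer, max_mm = 2L) {
  hits <- Biostrings::matchPattern(primer, Biostrings::DNAString(seq),
                                   max.mismatch = max_mm, with.indels = FALSE)
  if (length(hits) == 0L) return(NULL)
  c(start = Biostrings::start(hits)[[1L]] - 1L, end = Biostrings::end(hits)[[1L]])
}

#' Extract the informative amplicon interior
#'
#' Locates the forward primer and the reverse-complemented reverse primer
#' allowing at most 2 mismatches each, and returns the interior sequence
#' between them. Input orientation is normalized: if the primers are not
#' found on the given strand, the reverse complement is searched.
#'
#' @param gene_sequence nucleotide string containing the amplicon.
#' @param primer_pair a [primerPair()].
#' @param max_mm maximum mismatches per primer (default 2).
#' @return interior sequence, or `NULL` when either primer is not found.
#' @export
extractAmplicon <- function(gene_sequence, primer_pair, max_mm = 2L) {
  for (seq in c(toupper(gene_sequence), revComp(gene_sequence))) {
    f <- .find_primer(seq, primer_pair$forward, max_mm)
    if (is.null(f)) next
    r <- .find_primer(seq, revComp(primer_pair$reverse), max_mm)
    if (is.null(r) || r[["start"]] < f[["end"]]) next
    return(substr(seq, f[["end"]] + 1L, r[["start"]]))
  }
  NULL
}

#' Classify an amplicon against labeled reference alleles
#'
#' Nearest reference allele by global-alignment identity. The label is
#' returned when the best identity is at least `min_identity` (default
#' 98%) and all references within 0.5 points of the best share one label;
#' `"ambiguous"` when the top references disagree; `"novel"` when the best
#' identity is below the threshold.
#'
#' @param query_amplicon nucleotide string.
#' @param reference_alleles named character vector of alleles; names are
#'   genospecies labels (duplicated names = multiple alleles per label).
#' @param min_identity minimum identity percent (default 98).
#' @param tie_window identity window (points) within which references must
#'   agree (default 0.5).
#' @return list: `call` (label, `"ambiguous"` or `"novel"`),
#'   `best_identity`, `identities`.
#' @export
classifyByAlleles <- function(query_amplicon, reference_alleles,
                              min_identity = 98, tie_window = 0.5) {
  ids <- vapply(reference_alleles, function(ref)
    100 * globalAlign(query_amplicon, ref, type = "nt")$identity, 0)
  best <- max(ids)
  if (best < min_identity)
    return(list(call = "novel", best_identity = best, identities = ids))
  top <- names(ids)[ids >= best - tie_window]
  call <- if (length(unique(top)) == 1L) top[[1L]] else "ambiguous"
  list(call = call, best_identity = best, identities = ids)
}

#' Multi-gene amplicon classification
#'
#' Classifies each gene's amplicon separately and intersects the per-gene
#' labels (genes returning `"ambiguous"`/`"novel"` are uninformative). The
#' combined call is the single label all informative genes agree on,
#' `"ambiguous"` when they disagree or when no gene is informative.
#'
#' @param amplicons named list gene -> query amplicon.
#' @param references named list gene -> labeled reference alleles.
#' @param ... passed to [classifyByAlleles()].
#' @return list: `call`, `per_gene` (named character).
#' @export
classifyMultiGene <- function(amplicons, references, ...) {
  per_gene <- setNames(rep(NA_character_, length(amplicons)), names(amplicons))
  for (g in names(amplicons)) {
    if (is.null(amplicons[[g]])) next
    per_gene[[g]] <- classifyByAlleles(amplicons[[g]], references[[g]], ...)$call
  }
  informative <- per_gene[!is.na(per_gene) &
                            !per_gene %in% c("ambiguous", "novel")]
  # majority label across informative genes; ties -> ambiguous
  call <- if (!length(informative)) "ambiguous" else {
    tab <- sort(table(informative), decreasing = TRUE)
    if (length(tab) == 1L || tab[[1L]] > tab[[2L]]) names(tab)[[1L]] else "ambiguous"
  }
  list(call = call, per_gene = per_gene)
}
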