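#' @include genospecies.R
NULL

#' Core gene set definition
#'
#' An ordered set of core genes used for the concatenated phylogeny: gene
#' ids, reference protein sequences (search queries) and expected
#' nucleotide lengths, plus the reference nucleotide sequences used as
#' alignment anchors.
#'
#' @param proteins named character vector of reference protein sequences
#'   (unique names fix the concatenation order).
#' @param lengths named integer vector of expected nucleotide lengths.
#' @param nt named character vector of reference nucleotide sequences (the
#'   anchor for per-gene alignment).
#' @return list of class `coreGeneSet`.
#' @export
coreGeneSet <- function(proteins, lengths, nt) {
  stopifnot(!is.null(names(proteins)), !anyDuplicated(names(proteins)),
            all(names(proteins) %in% names(lengths)),
            all(names(proteins) %in% names(nt)))
  structure(list(genes = names(proteins), proteins = proteins,
                 lengths = lengths[names(proteins)], nt = nt[names(proteins)]),
            class = "coreGeneSet")
}

#' Extract core genes from one assembly
#'
#' For each gene: translated search of the reference protein against the
#' genome, then extension of the best hit to the expected nucleotide
#' length. Genes with no hit passing the cutoff are recorded as missing
#' (`NA`).
#'
#' @param genome a [GenomeAssembly-class].
#' @param core_set a [coreGeneSet()].
#' @param evalue E-value cutoff (default `1e-10`).
#' @return named character vector, gene -> nucleotide sequence (`NA` when
#'   missing).
#' @export
extractCoreGenes <- function(genome, core_set, evalue = 1e-10) {
  out <- setNames(rep(NA_character_, length(core_set$genes)), core_set$genes)
  frames <- genomeFrames(genome)
  for (g in core_set$genes) {
    hit <- translatedSearch(setNames(core_set$proteins[[g]], g), genome,
                            evalue_cutoff = evalue, frames_cache = frames)
    if (is.null(hit)) next
    out[[g]] <- extendHit(hit, core_set$lengths[[g]], genome)
  }
  out
}

#' Keep strains with (nearly) complete core-gene sets
#'
#' @param gene_maps named list (strain -> output of [extractCoreGenes()]).
#' @param required minimum number of present genes (default: all).
#' @return character vector of included strain ids.
#' @export
filterComplete <- function(gene_maps, required = NULL) {
  n_genes <- length(gene_maps[[1L]])
  if (is.null(required)) required <- n_genes
  keep <- vapply(gene_maps, function(m) sum(!is.na(m)) >= required, TRUE)
  names(gene_maps)[keep]
}

#' Reference-anchored per-gene alignment
#'
#' Each sequence is globally aligned to the reference gene (affine gaps)
#' and projected onto reference coordinates: insertions relative to the
#' reference are dropped, deletions become gap characters, so every row
#' has exactly the reference length.
#'
#' @param seqs named character vector of gene sequences.
#' @param reference reference nucleotide sequence.
#' @return character matrix (strains x reference positions, one character
#'   per cell), `length(reference)` columns.
#' @export
anchorAlign <- function(seqs, reference) {
  reflen <- nchar(reference)
  rows <- matrix("-", nrow = length(seqs), ncol = reflen,
                 dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    r <- globalAlign(seqs[[i]], reference, type = "nt")
    a <- strsplit(r$a_aln, "")[[1L]]
    b <- strsplit(r$b_aln, "")[[1L]]
    refpos <- cumsum(b != "-")
    keep <- b != "-"
    rows[i, refpos[keep]] <- a[keep]
  }
  rows
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' @param alignments named list of per-gene alignment matrices (from
#'   [anchorAlign()]), all with identical row names.
#' @param order gene order (default: list order).
#' @return list of class `supermatrix`: `matrix` (strain x columns),
#'   `spans` (data.frame gene, start, end; 0-based half-open column spans).
#' @export
concatenateGenes <- function(alignments, order = names(alignments)) {
  if (!length(alignments)) stop("empty gene list")
  strains <- rownames(alignments[[1L]])
  for (g in order) {
    miss <- setdiff(strains, rownames(alignments[[g]]))
    extra <- setdiff(rownames(alignments[[g]]), strains)
    if (length(miss) || length(extra))
      stop("strain missing from gene ", g, ": ",
           paste(c(miss, extra), collapse = ", "))
  }
  mats <- lapply(order, function(g) alignments[[g]][strains, , drop = FALSE])
  widths <- vapply(mats, ncol, 0L)
  ends <- cumsum(widths)
  spans <- data.frame(gene = order, start = c(0L, head(ends, -1L)), end = ends)
  structure(list(matrix = do.call(cbind, mats), spans = spans),
            class = "supermatrix")
}

#' Jukes-Cantor distances from a supermatrix
#'
#' For each pair of rows, `p` is the mismatch fraction over columns where
#' both rows are non-gap, and `d = -(3/4) * log(1 - 4p/3)`. A pair with
#' `p >= 0.75`, or with no shared non-gap columns, is an error.
#'
#' @param sm a supermatrix from [concatenateGenes()] (or a plain character
#'   matrix).
#' @return symmetric numeric distance matrix.
#' @export
jcDistance <- function(sm) {
  m <- if (inherits(sm, "supermatrix")) sm$matrix else sm
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  gap <- m == "-"
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok)) stop("no shared non-gap columns between ",
                       rownames(m)[[i]], " and ", rownames(m)[[j]])
    p <- mean(m[i, ok] != m[j, ok])
    if (p >= 0.75) stop("saturated distance (p >= 0.75) between ",
                        rownames(m)[[i]], " and ", rownames(m)[[j]])
    d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
  }
  d
}

#' Neighbor-joining tree rooted on an outgroup
#'
#' Canonical neighbor-joining on the distance matrix, negative branch
#' lengths clamped to zero, rooted on the outgroup edge.
#'
#' @param d symmetric distance matrix.
#' @param outgroup tip label to root on (`NULL` leaves the tree unrooted).
#' @return an [ape::phylo] tree.
#' @export
njTree <- function(d, outgroup = NULL) {
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  if (!is.null(outgroup)) {
    stopifnot(outgroup %in% tr$tip.label)
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  tr
}

#' Build the concatenated core-gene tree for a set of genomes
#'
#' Extraction, completeness filtering, reference-anchored alignment,
#' concatenation, Jukes-Cantor distances and neighbor joining in one call.
#'
#' @param genomes named list of [GenomeAssembly-class].
#' @param core_set a [coreGeneSet()].
#' @param outgroup optional strain id to root on.
#' @param genes optional subset of gene ids to use.
#' @param required minimum present genes per strain (default all of
#'   `genes`).
#' @param gene_maps optional precomputed [extractCoreGenes()] outputs (one
#'   per genome) to skip re-extraction.
#' @return list with `tree`, `supermatrix`, `distances`, `included`,
#'   `excluded`, `gene_maps`.
#' @export
corePhylogeny <- function(genomes, core_set, outgroup = NULL, genes = NULL,
                          required = NULL, gene_maps = NULL) {
  if (is.null(genes)) genes <- core_set$genes
  maps <- if (is.null(gene_maps))
    lapply(genomes, extractCoreGenes, core_set = core_set) else gene_maps
  maps <- lapply(maps, function(m) m[genes])
  included <- filterComplete(maps, required)
  excluded <- setdiff(names(maps), included)
  if (length(included) < 3L) stop("fewer than 3 strains with complete core genes")
  alns <- list()
  for (g in genes) {
    seqs <- vapply(included, function(s) maps[[s]][[g]], "")
    alns[[g]] <- anchorAlign(seqs, core_set$nt[[g]])
  }
  sm <- concatenateGenes(alns, genes)
  d <- jcDistance(sm)
  tr <- njTree(d, outgroup = if (!is.null(outgroup) && outgroup %in% included)
    outgroup else NULL)
  list(tree = tr, supermatrix = sm, distances = d, included = included,
       excluded = excluded, gene_maps = maps)
}

#' Split-half robustness trees
#'
#' Splits the gene set deterministically by position parity of the
#' gene-id order (odd-ranked genes vs even-ranked genes) and builds one
#' full tree per half.
#'
#' @inheritParams corePhylogeny
#' @param gene_maps optional precomputed extractions shared by both halves.
#' @return list with `tree_A`, `tree_B`, `genes_A`, `genes_B`.
#' @export
splitHalfTrees <- function(genomes, core_set, outgroup = NULL,
                           gene_maps = NULL) {
  genes <- sort(core_set$genes)
  ga <- genes[seq_along(genes) %% 2L == 1L]
  gb <- genes[seq_along(genes) %% 2L == 0L]
  if (is.null(gene_maps))
    gene_maps <- lapply(genomes, extractCoreGenes, core_set = core_set)
  ra <- corePhylogeny(genomes, core_set, outgroup = outgroup, genes = ga,
                      gene_maps = gene_maps)
  rb <- corePhylogeny(genomes, core_set, outgroup = outgroup, genes = gb,
                      gene_maps = gene_maps)
  list(tree_A = ra$tree, tree_B = rb$tree, genes_A = ga, genes_B = gb)
}

#' Gene-resampling bootstrap support
#'
#' Resamples whole genes with replacement (gene-level rather than
#' site-level bootstrap), rebuilds the NJ tree per replicate, and reports
#' per-node support for the reference tree as percentages via
#' [ape::prop.clades()].
#'
#' @param alignments named list of per-gene alignment matrices.
#' @param reference_tree the tree whose internal nodes receive support.
#' @param outgroup optional tip to root replicate trees on.
#' @param n number of replicates (default 100).
#' @param seed RNG seed.
#' @return the reference tree with `node.label` set to support percentages.
#' @export
geneBootstrapSupport <- function(alignments, reference_tree, outgroup = NULL,
                                 n = 100L, seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  reps <- vector("list", n)
  for (i in seq_len(n)) {
    pick <- sample(names(alignments), length(alignments), replace = TRUE)
    sm <- do.call(cbind, alignments[pick])
    d <- jcDistance(sm)
    reps[[i]] <- njTree(d, outgroup = outgroup)
  }
  pc <- ape::prop.clades(reference_tree, reps, rooted = FALSE)
  pc[is.na(pc)] <- 0
  reference_tree$node.label <- round(100 * pc / n)
  reference_tree
}

#' Check per-label monophyly in a rooted tree
#'
#' A label is monophyletic iff its strains form an exact clade; labels
#' with a single strain are monophyletic by convention.
#'
#' @param tree a rooted `phylo`.
#' @param partition named character (strain -> label) or a
#'   [GenospeciesPartition-class].
#' @return named logical vector, one entry per label.
#' @export
checkMonophyly <- function(tree, partition) {
  labs <- if (methods::is(partition, "GenospeciesPartition"))
    partition@labels else partition
  labs <- labs[names(labs) %in% tree$tip.label]
  out <- logical()
  for (lab in sort(unique(labs))) {
    tips <- names(labs)[labs == lab]
    out[[lab]] <- length(tips) == 1L || ape::is.monophyletic(tree, tips)
  }
  out
}

#' Export a supermatrix as FASTA or relaxed PHYLIP
#'
#' @param sm a supermatrix from [concatenateGenes()].
#' @param path output path.
#' @param format `"fasta"` or `"phylip"`.
#' @export
writeSupermatrix <- function(sm, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  seqs <- apply(sm$matrix, 1L, paste0, collapse = "")
  if (format == "fasta") {
    writeFasta(seqs, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%d %d", length(seqs), ncol(sm$matrix)), con)
    writeLines(sprintf("%s  %s", names(seqs), seqs), con)
  }
  invisible(path)
}
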