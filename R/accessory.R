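#' @include compartments.R
NULL

#' Call open reading frames and translate them
#'
#' Finds ORFs of at least `min_len_codons` codons (start to stop,
#' inclusive) on both strands: within each stop-to-stop frame segment the
#' longest ORF (earliest in-frame ATG/GTG/TTG start) is kept. Bacterial
#' table-11 semantics: alternative starts translate as methionine.
#'
#' @param genome a [GenomeAssembly-class].
#' @param min_len_codons minimum ORF length in codons, stop included
#'   (default 90).
#' @return named character vector of protein sequences (stop not
#'   included), names `strain|scaffold|start|end|strand` with 0-based
#'   half-open forward-strand coordinates.
#' @export
callOrfs <- function(genome, min_len_codons = 90L) {
  starts_ok <- c("ATG", "GTG", "TTG")
  out <- character()
  scafs <- scaffolds(genome)
  for (sid in names(scafs)) {
    fwd <- as.character(scafs[[sid]])
    slen <- nchar(fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else revComp(fwd)
      for (off in 0:2) {
        n_codons <- (nchar(s) - off) %/% 3L
        if (n_codons < min_len_codons) next
        pos <- off + seq.int(1L, by = 3L, length.out = n_codons)
        codons <- substring(s, pos, pos + 2L)
        stops <- which(codons %in% .STOPS)
        seg_start <- c(1L, stops + 1L)
        seg_stop <- c(stops, NA_integer_) # last segment has no stop: skip
        for (k in seq_along(seg_start)) {
          if (is.na(seg_stop[[k]])) next
          lo <- seg_start[[k]]; hi <- seg_stop[[k]]
          if (hi - lo + 1L < min_len_codons) next
          st <- which(codons[lo:hi] %in% starts_ok)
          if (!length(st)) next
          first <- lo + st[[1L]] - 1L
          if (hi - first + 1L < min_len_codons) next
          nt_lo <- pos[[first]] - 1L          # 0-based on strand s
          nt_hi <- pos[[hi]] + 2L             # half-open end
          orf_nt <- substr(s, nt_lo + 1L, nt_hi)
          prot <- sub("\\*$", "", translateDna(orf_nt))
          substr(prot, 1L, 1L) <- "M"
          if (strand == "+") { f_lo <- nt_lo; f_hi <- nt_hi }
          else { f_lo <- slen - nt_hi; f_hi <- slen - nt_lo }
          nm <- sprintf("%s|%s|%d|%d|%s", strainId(genome), sid, f_lo, f_hi, strand)
          out[[nm]] <- prot
        }
      }
    }
  }
  out
}

#' Build orthogroups by reciprocal best hits
#'
#' All-vs-all best protein hits between genomes define reciprocal-best-hit
#' edges; within-genome protein pairs at or above 80% identity add paralog
#' edges; single-linkage components are the orthogroups. Two copy-number
#' filters are then applied: orthogroups with more than two copies in any
#' one genome are excluded, and orthogroups present as a single copy in a
#' single genome are excluded.
#'
#' @param proteomes named list (genome -> named character vector of
#'   proteins, e.g. from [callOrfs()] or externally supplied).
#' @param paralog_identity within-genome identity threshold for paralog
#'   edges (default 0.8).
#' @return an [OrthogroupTable-class].
#' @export
buildOrthogroups <- function(proteomes, paralog_identity = 0.8) {
  gids <- names(proteomes)
  stopifnot(length(gids) >= 2L)
  # global protein index
  prot_genome <- rep(gids, vapply(proteomes, length, 0L))
  prot_name <- unlist(lapply(proteomes, names), use.names = FALSE)
  prot_seq <- unlist(proteomes, use.names = FALSE)
  np <- length(prot_seq)
  gidx <- split(seq_len(np), prot_genome)[gids]
  edges <- list()
  # between-genome reciprocal best hits
  for (a in seq_along(gids)) for (b in seq_along(gids)) {
    if (a >= b) next
    ia <- gidx[[a]]; ib <- gidx[[b]]
    ab <- .cpp_best_protein_hits(prot_seq[ia], prot_seq[ib])
    ba <- .cpp_best_protein_hits(prot_seq[ib], prot_seq[ia])
    for (q in seq_along(ia)) {
      tgt <- ab$best[[q]]
      if (is.na(tgt)) next
      back <- ba$best[[tgt]]
      if (!is.na(back) && back == q)
        edges[[length(edges) + 1L]] <- c(ia[[q]], ib[[tgt]])
    }
  }
  # within-genome paralog edges at >= 80% identity
  for (a in seq_along(gids)) {
    ia <- gidx[[a]]
    if (length(ia) < 2L) next
    for (x in seq_along(ia)) for (y in seq_along(ia)) {
      if (x >= y) next
      r <- .cpp_seeded_local(prot_seq[[ia[[x]]]], prot_seq[[ia[[y]]]], 4L, "aa")
      if (as.numeric(r[["score"]]) <= 0) next
      # identity over the longer protein, so short spurious repeats don't link
      cov_id <- as.numeric(r[["matches"]]) /
        max(nchar(prot_seq[[ia[[x]]]]), nchar(prot_seq[[ia[[y]]]]))
      if (cov_id >= paralog_identity)
        edges[[length(edges) + 1L]] <- c(ia[[x]], ia[[y]])
    }
  }
  g <- igraph::make_empty_graph(n = np, directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, as.vector(t(do.call(rbind, edges))))
  memb <- igraph::components(g)$membership
  counts <- table(factor(memb), factor(prot_genome, levels = gids))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = list(sprintf("OG%06d", seq_len(nrow(counts))), gids))
  # filters
  keep <- apply(counts, 1L, max) <= 2L &
    !(rowSums(counts > 0) == 1L & rowSums(counts) == 1L)
  methods::new("OrthogroupTable", counts = counts[keep, , drop = FALSE])
}

#' Normalized gene-sharing index between two strains
#'
#' With `S` the orthogroups present (count >= 1) in both strains and
#' `|A|`, `|B|` the orthogroups present in each, the index is
#' `(|S|/|A| + |S|/|B|) / 2`.
#'
#' @param strain_a,strain_b genome ids present in the table.
#' @param table an [OrthogroupTable-class].
#' @return fraction in `[0, 1]`.
#' @export
sharingIndex <- function(strain_a, strain_b, table) {
  m <- orthogroupCounts(table)
  stopifnot(strain_a %in% colnames(m), strain_b %in% colnames(m))
  a <- m[, strain_a] > 0
  b <- m[, strain_b] > 0
  if (!any(a) || !any(b)) stop("strain with zero orthogroups")
  s <- sum(a & b)
  (s / sum(a) + s / sum(b)) / 2
}

#' Gene sharing versus ANI across strain pairs
#'
#' Joins the sharing index with symmetrized ANI for every (or the given)
#' strain pairs and reports the Spearman rank correlation (`NA` when
#' undefined: fewer than two pairs or constant values).
#'
#' @param table an [OrthogroupTable-class].
#' @param ani_matrix symmetric ANI matrix.
#' @param pairs optional two-column matrix/data.frame of strain pairs;
#'   default: all pairs present in both inputs.
#' @return list with `records` (data.frame strain_a, strain_b, shared,
#'   index, ani) and `rho`.
#' @export
sharingVsAni <- function(table, ani_matrix, pairs = NULL) {
  m <- orthogroupCounts(table)
  ids <- intersect(colnames(m), rownames(ani_matrix))
  if (is.null(pairs)) {
    pairs <- t(utils::combn(ids, 2L))
  }
  recs <- data.frame(strain_a = pairs[, 1L], strain_b = pairs[, 2L],
                     shared = NA_integer_, index = NA_real_, ani = NA_real_,
                     stringsAsFactors = FALSE)
  for (k in seq_len(nrow(recs))) {
    a <- recs$strain_a[[k]]; b <- recs$strain_b[[k]]
    recs$shared[[k]] <- sum(m[, a] > 0 & m[, b] > 0)
    recs$index[[k]] <- sharingIndex(a, b, table)
    recs$ani[[k]] <- ani_matrix[a, b]
  }
  ok <- !is.na(recs$ani)
  rho <- if (sum(ok) >= 2L && stats::sd(recs$index[ok]) > 0 &&
             stats::sd(recs$ani[ok]) > 0)
    stats::cor(recs$index[ok], recs$ani[ok], method = "spearman") else NA_real_
  list(records = recs, rho = rho)
}

#' Write an orthogroup count table as TSV
#'
#' Column layout follows the conventional `Orthogroups.GeneCount.tsv`
#' dialect: one row per orthogroup, one column per genome, plus a total.
#'
#' @param table an [OrthogroupTable-class].
#' @param path output path.
#' @export
writeOrthogroups <- function(table, path) {
  m <- orthogroupCounts(table)
  df <- data.frame(Orthogroup = rownames(m), m, Total = rowSums(m),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
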