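#' @include ani.R
NULL

#' Partition parameters for genospecies delineation
#'
#' @param species_threshold ANI percent above which strains are linked into
#'   one genospecies (default 96).
#' @param compactness_threshold ANI percent above which a subcluster counts
#'   as compact during refinement (default 98).
#' @param gap_window percent interval scanned for the boundary gap
#'   (default `c(94.5, 97.5)`).
#' @return list of class `partitionParams`.
#' @export
partitionParams <- function(species_threshold = 96, compactness_threshold = 98,
                            gap_window = c(94.5, 97.5)) {
  stopifnot(compactness_threshold > species_threshold,
            gap_window[[1L]] <= species_threshold,
            species_threshold <= gap_window[[2L]])
  structure(list(species_threshold = species_threshold,
                 compactness_threshold = compactness_threshold,
                 gap_window = gap_window),
            class = "partitionParams")
}

#' Single-linkage components above an ANI threshold
#'
#' Connected components of the graph with an edge wherever symmetrized ANI
#' is at or above the threshold; undefined (`NA`) entries contribute no
#' edge; singletons are allowed.
#'
#' @param mat symmetric ANI matrix with diagonal 100.
#' @param threshold ANI percent.
#' @return list of character vectors of strain ids (sorted, components
#'   ordered by their first member).
#' @export
linkageComponents <- function(mat, threshold = 96) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  adj <- !is.na(mat) & mat >= threshold
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  out <- split(rownames(mat), comp)
  out <- lapply(out, sort)
  names(out) <- NULL
  out[order(vapply(out, `[[`, "", 1L))]
}

# all pairwise values of a subcluster at or above a threshold?
.is_compact <- function(members, mat, thr) {
  if (length(members) < 2L) return(TRUE)
  sub <- mat[members, members]
  vals <- sub[upper.tri(sub)]
  all(!is.na(vals) & vals >= thr)
}

# cophenetic (path-length) distances between tree leaves
.tree_dist <- function(tree) ape::cophenetic.phylo(tree)

#' Refine single-linkage components into a genospecies partition
#'
#' Within each component, complete-linkage subclusters are cut at the
#' species threshold. A component is split when (i) at least one subcluster
#' is compact (all pairwise ANI at or above `compactness_threshold`) and
#' (ii) every resulting subcluster is monophyletic in the tree; strains
#' that still bridge above the species threshold across subclusters are
#' assigned to the subcluster of their closest tree neighbour. Otherwise
#' the component stays whole. Components of size one, and strains left in a
#' subcluster of size one after a split, become unplaced.
#'
#' @param components output of [linkageComponents()].
#' @param mat symmetric ANI matrix.
#' @param tree rooted `phylo` tree containing every strain in `components`.
#' @param params a [partitionParams()] object.
#' @return a [GenospeciesPartition-class] (gap bounds filled by
#'   [delineateGenospecies()]).
#' @export
refineComponents <- function(components, mat, tree, params = partitionParams()) {
  strains <- unlist(components)
  missing <- setdiff(strains, tree$tip.label)
  if (length(missing)) stop("strain missing from tree: ", missing[[1L]])
  td <- .tree_dist(tree)
  labels <- character(); unplaced <- character()
  next_label <- 0L
  for (comp in components) {
    if (length(comp) == 1L) { unplaced <- c(unplaced, comp); next }
    sub <- mat[comp, comp]
    d <- 100 - sub
    d[is.na(d)] <- 100 # undefined ANI = maximal distance
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    cut <- stats::cutree(hc, h = 100 - params$species_threshold)
    groups <- split(comp, cut)
    do_split <- FALSE
    if (length(groups) >= 2L) {
      any_compact <- any(vapply(groups, .is_compact, TRUE,
                                mat = mat, thr = params$compactness_threshold))
      # bridge re-assignment by closest tree neighbour, then re-check
      if (any_compact) {
        assign_of <- cut
        for (s in comp) {
          own <- assign_of[[s]]
          others <- comp[assign_of[comp] != own]
          if (!length(others)) next
          cross <- mat[s, others]
          if (any(!is.na(cross) & cross >= params$species_threshold)) {
            nb <- comp[comp != s][which.min(td[s, comp[comp != s]])]
            assign_of[[s]] <- assign_of[[nb]]
          }
        }
        groups2 <- split(comp, assign_of)
        groups2 <- groups2[vapply(groups2, length, 0L) > 0L]
        mono <- all(vapply(groups2, function(g)
          length(g) == 1L || ape::is.monophyletic(tree, g), TRUE))
        if (mono && length(groups2) >= 2L &&
            any(vapply(groups2, .is_compact, TRUE,
                       mat = mat, thr = params$compactness_threshold))) {
          do_split <- TRUE
          groups <- groups2
        }
      }
    }
    if (!do_split) groups <- list(comp)
    for (g in groups) {
      if (length(g) == 1L && do_split) { unplaced <- c(unplaced, g); next }
      next_label <- next_label + 1L
      labels[g] <- sprintf("GS%02d", next_label)
    }
  }
  reps <- character()
  for (lab in unique(labels)) {
    members <- names(labels)[labels == lab]
    reps[[lab]] <- selectRepresentative(members, mat)
  }
  methods::new("GenospeciesPartition", labels = labels,
               representatives = reps, unplaced = unname(unplaced),
               gaps = data.frame(label = character(), gap_low = numeric(),
                                 gap_high = numeric()))
}

#' Detect the ANI boundary gap around a reference strain
#'
#' Sorts all defined ANI values to the reference in descending order and
#' returns the bounds of the largest empty interval between consecutive
#' values that intersects the window; `NULL` when no two consecutive values
#' fall inside or straddle the window.
#'
#' @param reference_strain strain id present in `mat`.
#' @param mat symmetric ANI matrix.
#' @param window percent interval to scan (default `c(94.5, 97.5)`).
#' @return numeric `c(gap_low, gap_high)` or `NULL`.
#' @export
detectGap <- function(reference_strain, mat, window = c(94.5, 97.5)) {
  stopifnot(reference_strain %in% rownames(mat))
  vals <- mat[reference_strain, setdiff(colnames(mat), reference_strain)]
  vals <- sort(vals[!is.na(vals)], decreasing = TRUE)
  if (length(vals) < 2L) return(NULL)
  lo <- vals[-1L]; hi <- vals[-length(vals)]
  keep <- lo < window[[2L]] & hi > window[[1L]] & hi > lo
  if (!any(keep)) return(NULL)
  width <- hi - lo
  width[!keep] <- -Inf
  i <- which.max(width)
  c(gap_low = unname(lo[[i]]), gap_high = unname(hi[[i]]))
}

#' Medoid representative of a cluster
#'
#' The strain maximizing mean symmetrized ANI to the other cluster
#' members; ties broken by lexicographically smaller id.
#'
#' @param cluster character vector of strain ids.
#' @param mat symmetric ANI matrix.
#' @return a strain id.
#' @export
selectRepresentative <- function(cluster, mat) {
  if (length(cluster) == 1L) return(cluster)
  means <- vapply(cluster, function(s)
    mean(mat[s, setdiff(cluster, s)], na.rm = TRUE), 0)
  cand <- sort(cluster[means == max(means)])
  cand[[1L]]
}

#' Full genospecies delineation from an ANI matrix and tree
#'
#' Runs [linkageComponents()], [refineComponents()], computes each
#' genospecies' boundary gap via [detectGap()] on its representative, and
#' returns the completed partition.
#'
#' @inheritParams refineComponents
#' @param mat symmetric ANI matrix.
#' @return a [GenospeciesPartition-class].
#' @export
delineateGenospecies <- function(mat, tree, params = partitionParams()) {
  comps <- linkageComponents(mat, params$species_threshold)
  part <- refineComponents(comps, mat, tree, params)
  gaps <- list()
  for (lab in names(part@representatives)) {
    g <- detectGap(part@representatives[[lab]], mat, params$gap_window)
    gaps[[lab]] <- data.frame(label = lab,
                              gap_low = if (is.null(g)) NA_real_ else g[["gap_low"]],
                              gap_high = if (is.null(g)) NA_real_ else g[["gap_high"]])
  }
  part@gaps <- if (length(gaps)) do.call(rbind, gaps) else part@gaps
  rownames(part@gaps) <- NULL
  part
}

#' Classify a new strain against an existing partition
#'
#' Computes ANI to each genospecies representative and assigns the label
#' whose representative ANI is maximal and at or above the species
#' threshold; otherwise `"unplaced"`.
#'
#' @param new_genome a [GenomeAssembly-class].
#' @param partition a [GenospeciesPartition-class].
#' @param genomes named list of [GenomeAssembly-class] containing the
#'   representatives.
#' @param params a [partitionParams()] object.
#' @param ani_params an [aniParams()] object.
#' @return a genospecies label or `"unplaced"`.
#' @export
classifyStrain <- function(new_genome, partition, genomes,
                           params = partitionParams(),
                           ani_params = aniParams()) {
  reps <- partition@representatives
  vals <- vapply(names(reps), function(lab) {
    ref <- genomes[[reps[[lab]]]]
    a <- aniPair(new_genome, ref, ani_params)$ani
    b <- aniPair(ref, new_genome, ani_params)$ani
    v <- c(a, b); v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  if (all(is.na(vals))) return("unplaced")
  best <- which.max(vals)
  if (vals[[best]] >= params$species_threshold) names(reps)[[best]] else "unplaced"
}

#' Compare two partitions (adjusted Rand index)
#'
#' Standard ARI over the strains present in both partitions, plus a
#' cluster-level contingency mapping reporting merges and splits.
#'
#' @param p1,p2 named character vectors (strain -> label) or
#'   [GenospeciesPartition-class] objects (placed strains only).
#' @return list with `ari` and `mapping` (contingency data.frame).
#' @export
comparePartitions <- function(p1, p2) {
  lab <- function(p) if (methods::is(p, "GenospeciesPartition")) p@labels else p
  p1 <- lab(p1); p2 <- lab(p2)
  common <- intersect(names(p1), names(p2))
  if (!length(common)) stop("no strains in common")
  a <- p1[common]; b <- p2[common]
  tab <- table(a, b)
  comb2 <- function(x) sum(choose(x, 2))
  n <- length(common)
  sum_ij <- comb2(as.vector(tab))
  sum_a <- comb2(rowSums(tab))
  sum_b <- comb2(colSums(tab))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  ari <- if (maxi == expected) {
    if (sum_ij == maxi) 1 else 0 # degenerate: both partitions trivial
  } else (sum_ij - expected) / (maxi - expected)
  mp <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(mp) <- c("label1", "label2", "n")
  mp <- mp[mp$n > 0, ]
  rownames(mp) <- NULL
  list(ari = ari, mapping = mp)
}

#' Write a genospecies partition as TSV + JSON gap sidecar
#'
#' @param partition a [GenospeciesPartition-class].
#' @param tsv_path,json_path output paths (either may be `NULL`).
#' @export
writePartition <- function(partition, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    placed <- data.frame(strain = names(partition@labels),
                         label = unname(partition@labels),
                         representative_flag = names(partition@labels) %in%
                           partition@representatives,
                         unplaced_flag = FALSE, stringsAsFactors = FALSE)
    nu <- length(partition@unplaced)
    unp <- data.frame(strain = partition@unplaced,
                      label = rep("", nu),
                      representative_flag = rep(FALSE, nu),
                      unplaced_flag = rep(TRUE, nu),
                      stringsAsFactors = FALSE)
    write.table(rbind(placed, unp), tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(json_path))
    jsonlite::write_json(partition@gaps, json_path, auto_unbox = FALSE,
                         digits = NA, na = "null")
  invisible(NULL)
}
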