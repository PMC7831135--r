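#' @include markers.R
NULL

#' Run the full delineation pipeline
#'
#' Orchestrates simulate (or ingest) -> ANI matrix -> core-gene phylogeny
#' -> genospecies delineation -> compartments -> orthogroups/sharing ->
#' markers, and writes every stage's artifact plus a per-strain and a
#' per-genospecies report to `out_dir`. Fully deterministic under a fixed
#' seed, including file ordering.
#'
#' @param sim_config a [simConfig()] (simulate mode), or `NULL` with
#'   `genomes_dir` set (ingest mode; ingest mode needs `refs` supplied).
#' @param genomes_dir directory of per-strain FASTA files (ingest mode).
#' @param refs reference inputs as produced by [simulateComplex()]
#'   (`$refs`); required in ingest mode.
#' @param out_dir output directory.
#' @param ani_params an [aniParams()].
#' @param partition_params a [partitionParams()].
#' @param min_markers chromosomal call threshold (default 1).
#' @param run_accessory,run_markers stage toggles.
#' @return list with all stage results (invisible copies of what was
#'   written): `genomes`, `truth` (simulate mode), `ani`, `phylo`,
#'   `partition`, `compartments`, `orthogroups`, `sharing`, `symbiovars`,
#'   `strain_report`, `genospecies_report`.
#' @export
runPipeline <- function(sim_config = NULL, genomes_dir = NULL, refs = NULL,
                        out_dir, ani_params = aniParams(),
                        partition_params = partitionParams(),
                        min_markers = 1L, run_accessory = TRUE,
                        run_markers = TRUE) {
  if (is.null(sim_config) == is.null(genomes_dir))
    stop("exactly one of sim_config or genomes_dir must be given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (!is.null(sim_config)) {
    sim <- simulateComplex(sim_config)
    genomes <- sim$genomes
    truth <- sim$truth
    refs <- sim$refs
    writeGenomesDir(genomes, file.path(out_dir, "genomes"))
    writeTruth(truth, file.path(out_dir, "truth"))
  } else {
    if (is.null(refs)) stop("ingest mode needs refs (core proteins, markers, ...)")
    genomes <- readGenomesDir(genomes_dir)
  }
  genomes <- genomes[sort(names(genomes))]

  ani <- aniMatrix(genomes, ani_params)
  writeAniMatrix(ani, file.path(out_dir, "ani_matrix.tsv"),
                 file.path(out_dir, "ani_long.tsv"))

  core_set <- coreGeneSet(refs$core_proteins, refs$core_lengths, refs$core_nt)
  outg <- if ("outgroup" %in% names(genomes)) "outgroup" else NULL
  phylo <- corePhylogeny(genomes, core_set, outgroup = outg)
  ape::write.tree(phylo$tree, file.path(out_dir, "core_tree.nwk"))
  writeSupermatrix(phylo$supermatrix, file.path(out_dir, "supermatrix.fasta"))

  partition <- delineateGenospecies(ani$matrix, phylo$tree, partition_params)
  writePartition(partition, file.path(out_dir, "partition.tsv"),
                 file.path(out_dir, "partition_gaps.json"))

  comp <- do.call(rbind, lapply(genomes, classifyScaffolds,
                                marker_genes = refs$marker_genes,
                                min_markers = min_markers))
  rownames(comp) <- NULL
  write.table(comp, file.path(out_dir, "compartments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  og <- NULL; sharing <- NULL
  if (run_accessory) {
    proteomes <- lapply(genomes, callOrfs)
    og <- buildOrthogroups(proteomes)
    writeOrthogroups(og, file.path(out_dir, "orthogroups.tsv"))
    sharing <- sharingVsAni(og, ani$matrix)
    write.table(sharing$records, file.path(out_dir, "sharing.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, na = "NA")
  }

  sv <- NULL; hap <- NULL
  if (run_markers) {
    sv <- lapply(genomes, assignSymbiovar,
                 nod_references = refs$nod_proteins)
    svdf <- data.frame(strain = names(sv),
                       call = vapply(sv, function(x) x$call, ""),
                       t(vapply(sv, function(x) x$genes, character(4L))),
                       stringsAsFactors = FALSE, row.names = NULL)
    write.table(svdf, file.path(out_dir, "symbiovar.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, na = "NA")
    profs <- list()
    for (s in names(genomes)) {
      x <- extract16S(genomes[[s]], refs$standard_16s)
      if (!is.null(x) && !x$incomplete)
        profs[[s]] <- profile16S(x$seq, refs$standard_16s)
    }
    hap <- if (length(profs)) catalogHaplotypes(profs) else
      data.frame(strain = character(), haplotype = character())
    write.table(hap, file.path(out_dir, "sixteens_haplotypes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # per-strain report
  labels <- gsLabels(partition)
  strain_report <- data.frame(strain = names(genomes), stringsAsFactors = FALSE)
  strain_report$genospecies <- ifelse(strain_report$strain %in% names(labels),
                                      labels[strain_report$strain], "unplaced")
  strain_report$representative <- strain_report$strain %in%
    representatives(partition)
  strain_report$symbiovar <- if (!is.null(sv))
    vapply(sv[strain_report$strain], function(x) x$call, "") else NA_character_
  strain_report$haplotype_16s <- if (!is.null(hap))
    hap$haplotype[match(strain_report$strain, hap$strain)] else NA_character_
  strain_report$chromosomal_nt <- vapply(strain_report$strain, function(s)
    sum(comp$length[comp$strain == s & comp$compartment == "chromosomal"]), 0)
  strain_report$plasmid_nt <- vapply(strain_report$strain, function(s)
    sum(comp$length[comp$strain == s & comp$compartment == "plasmid"]), 0)
  strain_report$mean_within_sharing <- NA_real_
  if (!is.null(sharing)) {
    rec <- sharing$records
    for (k in seq_len(nrow(strain_report))) {
      s <- strain_report$strain[[k]]
      lab <- strain_report$genospecies[[k]]
      if (lab == "unplaced") next
      mates <- setdiff(names(labels)[labels == lab], s)
      v <- rec$index[(rec$strain_a == s & rec$strain_b %in% mates) |
                       (rec$strain_b == s & rec$strain_a %in% mates)]
      if (length(v)) strain_report$mean_within_sharing[[k]] <- mean(v)
    }
  }
  write.table(strain_report, file.path(out_dir, "report_strains.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")

  # per-genospecies report
  mono <- checkMonophyly(phylo$tree, partition)
  gaps <- gapBounds(partition)
  gs_report <- data.frame(label = names(representatives(partition)),
                          stringsAsFactors = FALSE)
  gs_report$size <- vapply(gs_report$label, function(l) sum(labels == l), 0L)
  gs_report$representative <- representatives(partition)[gs_report$label]
  gs_report$gap_low <- gaps$gap_low[match(gs_report$label, gaps$label)]
  gs_report$gap_high <- gaps$gap_high[match(gs_report$label, gaps$label)]
  gs_report$monophyletic <- mono[gs_report$label]
  write.table(gs_report, file.path(out_dir, "report_genospecies.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")

  invisible(list(genomes = genomes, truth = truth, ani = ani, phylo = phylo,
                 partition = partition, compartments = comp,
                 orthogroups = og, sharing = sharing, symbiovars = sv,
                 strain_report = strain_report,
                 genospecies_report = gs_report))
}
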