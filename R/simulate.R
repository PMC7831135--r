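#' @include search.R
NULL

#' Simulation configuration for a synthetic species complex
#'
#' Builds the parameter set for [simulateComplex()]. Divergences are
#' pairwise substitution distances between lineages (star topology:
#' branches carry half the pairwise value), so two strains separated by
#' divergence `d` have expected raw identity `1 - d` and expected ANI
#' `100 * (1 - d)`. Where a divergence is given as a range `c(lo, hi)`, a
#' per-genospecies value is drawn uniformly from it.
#'
#' @param n_genospecies number of genospecies.
#' @param strains_per_gs strains per genospecies (scalar or vector of
#'   length `n_genospecies`).
#' @param chrom_len ancestor chromosome length (nt). The default 200 kb is
#'   the package's desk-scale stand-in for the ~5 Mb chromosomes of real
#'   rhizobial genomes.
#' @param n_chrom_scaffolds number of scaffolds the chromosome is split into.
#' @param n_plasmids,plasmid_len plasmid compartment: count and length each.
#' @param between_gs_divergence pairwise divergence between genospecies
#'   (default range 0.045-0.08, i.e. between-genospecies ANI ~92-95.5%).
#' @param within_gs_divergence pairwise divergence within a genospecies
#'   (default range 0.005-0.02, within-ANI ~98-99.5%).
#' @param outgroup whether to add one outgroup strain.
#' @param outgroup_divergence pairwise divergence outgroup vs ingroup
#'   (default 0.085, ANI ~91.5%).
#' @param plasmid_rate_multiplier plasmid substitution rate relative to the
#'   chromosome (default 1.5).
#' @param n_core_genes,core_gene_len universal core genes planted in the
#'   chromosome (defaults 120 x 900 nt).
#' @param n_chrom_markers,marker_len chromosomal marker genes (default 40,
#'   a desk-scale stand-in for the 3215-gene chromosomal marker list).
#' @param n_isolates number of isolated singleton strains (each its own
#'   deeply diverged lineage).
#' @param isolate_divergence pairwise divergence of isolates vs ingroup.
#' @param accessory_pool_per_gs accessory genes in each genospecies pool.
#' @param accessory_gene_len accessory gene length (nt).
#' @param accessory_retain_prob probability a strain retains an accessory
#'   gene of its own genospecies pool.
#' @param accessory_share_decay exponential decay of the retention
#'   probability with donor-recipient divergence (per substitution/site).
#' @param n_introgressions number of housekeeping-allele introgression
#'   events (donor allele from another genospecies overwrites a recipient's
#'   gene).
#' @param symbiovar_assignment per-strain symbiovar labels in
#'   `c("viciae","trifolii","phaseoli","none")`, recycled; `NULL` cycles
#'   through all four.
#' @param indel_rate small-indel rate per site (0 = substitution-only
#'   default; indels have geometric length, mean 2).
#' @param seed integer seed fixing the whole output byte-for-byte.
#' @return a list of class `simConfig`.
#' @export
simConfig <- function(n_genospecies = 3L, strains_per_gs = 3L,
                      chrom_len = 200000L, n_chrom_scaffolds = 2L,
                      n_plasmids = 2L, plasmid_len = 50000L,
                      between_gs_divergence = c(0.045, 0.08),
                      within_gs_divergence = c(0.005, 0.02),
                      outgroup = FALSE, outgroup_divergence = 0.085,
                      plasmid_rate_multiplier = 1.5,
                      n_core_genes = 120L, core_gene_len = 900L,
                      n_chrom_markers = 40L, marker_len = 600L,
                      n_isolates = 0L, isolate_divergence = 0.10,
                      accessory_pool_per_gs = 0L, accessory_gene_len = 900L,
                      accessory_retain_prob = 0.9,
                      accessory_share_decay = 25,
                      n_introgressions = 0L,
                      symbiovar_assignment = NULL,
                      indel_rate = 0, seed = 1L) {
  cfg <- list(n_genospecies = as.integer(n_genospecies),
              strains_per_gs = as.integer(strains_per_gs),
              chrom_len = as.integer(chrom_len),
              n_chrom_scaffolds = as.integer(n_chrom_scaffolds),
              n_plasmids = as.integer(n_plasmids),
              plasmid_len = as.integer(plasmid_len),
              between_gs_divergence = as.numeric(between_gs_divergence),
              within_gs_divergence = as.numeric(within_gs_divergence),
              outgroup = isTRUE(outgroup),
              outgroup_divergence = as.numeric(outgroup_divergence),
              plasmid_rate_multiplier = as.numeric(plasmid_rate_multiplier),
              n_core_genes = as.integer(n_core_genes),
              core_gene_len = as.integer(core_gene_len),
              n_chrom_markers = as.integer(n_chrom_markers),
              marker_len = as.integer(marker_len),
              n_isolates = as.integer(n_isolates),
              isolate_divergence = as.numeric(isolate_divergence),
              accessory_pool_per_gs = as.integer(accessory_pool_per_gs),
              accessory_gene_len = as.integer(accessory_gene_len),
              accessory_retain_prob = as.numeric(accessory_retain_prob),
              accessory_share_decay = as.numeric(accessory_share_decay),
              n_introgressions = as.integer(n_introgressions),
              symbiovar_assignment = symbiovar_assignment,
              indel_rate = as.numeric(indel_rate),
              seed = as.integer(seed))
  stopifnot(cfg$n_genospecies >= 1, all(cfg$strains_per_gs >= 1),
            cfg$chrom_len > 0, cfg$plasmid_len > 0 || cfg$n_plasmids == 0,
            all(cfg$between_gs_divergence > 0 & cfg$between_gs_divergence < 0.3),
            all(cfg$within_gs_divergence > 0 & cfg$within_gs_divergence < 0.3),
            cfg$core_gene_len %% 3 == 0)
  # feature payload must fit the chromosome with room for spacers
  payload <- cfg$n_core_genes * cfg$core_gene_len +
    cfg$n_chrom_markers * cfg$marker_len + 574L + 759L + 642L + 1500L
  if (payload > 0.9 * cfg$chrom_len)
    stop("chromosome features (", payload, " nt) exceed 90% of chrom_len; ",
         "reduce gene counts or lengths, or enlarge chrom_len")
  class(cfg) <- "simConfig"
  cfg
}

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

.random_dna <- function(n) paste0(sample(.BASES, n, replace = TRUE), collapse = "")

# random protein-coding gene: ATG start, non-stop interior codons, one stop
.random_gene <- function(len_nt) {
  n_codons <- len_nt %/% 3L
  codons <- character(n_codons)
  codons[1L] <- "ATG"
  sense <- setdiff(apply(expand.grid(.BASES, .BASES, .BASES), 1, paste0, collapse = ""),
                   .STOPS)
  codons[seq(2L, n_codons - 1L)] <- sample(sense, n_codons - 2L, replace = TRUE)
  codons[n_codons] <- "TAA"
  paste0(codons, collapse = "")
}

#' Mutate a sequence under a uniform substitution model
#'
#' Each site is substituted independently with probability `d`, uniformly
#' to one of the other three bases (Jukes-Cantor-style). With
#' `indel_rate > 0`, small insertions/deletions (geometric length, mean 2)
#' are additionally introduced.
#'
#' Uses R's global RNG stream; seed with `set.seed()` for reproducibility.
#'
#' @param seq nucleotide string.
#' @param d per-site substitution probability, in `[0, 0.75)`.
#' @param indel_rate per-site indel probability (default 0).
#' @return mutated nucleotide string.
#' @export
mutateSeq <- function(seq, d, indel_rate = 0) {
  if (d < 0 || d >= 0.75) stop("d must be in [0, 0.75)")
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(x)
  if (d > 0) {
    hit <- which(stats::runif(n) < d)
    if (length(hit)) {
      # uniform over the three other bases
      cur <- x[hit]
      alt <- vapply(cur, function(b) sample(setdiff(.BASES, b), 1L), "")
      x[hit] <- alt
    }
  }
  if (indel_rate > 0) {
    ev <- which(stats::runif(n) < indel_rate)
    if (length(ev)) {
      parts <- x
      for (i in ev) {
        len <- stats::rgeom(1L, 0.5) + 1L
        if (stats::runif(1L) < 0.5) { # deletion: blank len sites from i
          parts[seq(i, min(n, i + len - 1L))] <- ""
        } else {                      # insertion after site i
          parts[i] <- paste0(parts[i],
                             paste0(sample(.BASES, len, replace = TRUE), collapse = ""))
        }
      }
      x <- parts
    }
  }
  paste0(x, collapse = "")
}

# mutate a coding sequence, then revert any codon that acquired an internal
# stop (keeps reference proteins translatable; slight rate shrink is
# irrelevant at the d values used)
.mutate_coding <- function(seq, d) {
  out <- mutateSeq(seq, d)
  n_codons <- nchar(out) %/% 3L
  st <- seq.int(1L, by = 3L, length.out = n_codons)
  codons <- substring(out, st, st + 2L)
  bad <- which(codons[-n_codons] %in% .STOPS)
  if (length(bad)) {
    orig <- substring(seq, st, st + 2L)
    codons[bad] <- orig[bad]
    out <- paste0(codons, collapse = "")
  }
  out
}

# A genome blueprint is an ordered list of segments, each
# list(name, kind, seq); kind in spacer/core/marker/hk/sixteens.
.build_chrom_blueprint <- function(cfg) {
  feats <- list()
  add <- function(name, kind, seq) feats[[length(feats) + 1L]] <<- list(name = name, kind = kind, seq = seq)
  for (i in seq_len(cfg$n_core_genes))
    add(sprintf("core%03d", i), "core", .random_gene(cfg$core_gene_len))
  for (i in seq_len(cfg$n_chrom_markers))
    add(sprintf("marker%03d", i), "marker", .random_gene(cfg$marker_len))
  # housekeeping amplicon genes: fwd primer + informative interior + rc(rev primer)
  hk <- list(atpD = 534L, gyrB = 719L, recA = 602L)
  primers <- list()
  for (g in names(hk)) {
    pf <- .random_dna(20L); pr <- .random_dna(20L)
    primers[[g]] <- list(gene = g, forward = pf, reverse = pr,
                         informative_len = hk[[g]])
    add(g, "hk", paste0(pf, .random_dna(hk[[g]]), revComp(pr)))
  }
  add("rrs16S", "sixteens", .random_dna(1500L))
  # interleave deterministically-shuffled features with spacers
  feats <- feats[sample(length(feats))]
  payload <- sum(vapply(feats, function(f) nchar(f$seq), 0))
  n_spacers <- length(feats) + 1L
  spacer_total <- cfg$chrom_len - payload
  sp_len <- diff(round(seq(0, spacer_total, length.out = n_spacers + 1L)))
  out <- list(list(name = "spacer0", kind = "spacer", seq = .random_dna(sp_len[[1L]])))
  for (i in seq_along(feats)) {
    out[[length(out) + 1L]] <- feats[[i]]
    out[[length(out) + 1L]] <- list(name = sprintf("spacer%d", i), kind = "spacer",
                                    seq = .random_dna(sp_len[[i + 1L]]))
  }
  list(segments = out, primers = primers)
}

# nod cassette: 4 genes x 3 symbiovar allele variants
.build_nod_alleles <- function() {
  genes <- c("nodD", "nodA", "nodB", "nodC")
  base <- lapply(setNames(genes, genes), function(g) .random_gene(600L))
  svs <- c("viciae", "trifolii", "phaseoli")
  out <- list()
  for (sv in svs)
    out[[sv]] <- lapply(base, .mutate_coding, d = 0.15)
  out
}

#' Simulate a synthetic species complex with known truth
#'
#' Builds one random ancestor genome (chromosome with embedded core genes,
#' chromosomal marker genes, housekeeping genes and a 16S copy; plasmids
#' with genospecies-specific accessory genes and, for symbiotic strains, a
#' nod cassette), derives one lineage per genospecies and per isolate, then
#' strains within each genospecies (star topology). Plasmid sites mutate at
#' `plasmid_rate_multiplier` times the chromosomal rate. Scaffolds are
#' emitted shuffled and renamed so compartments are not inferable from
#' names. The full ground truth and all reference inputs (core proteins,
#' marker genes, housekeeping alleles per genospecies, nod reference
#' proteins, primer pairs, the 16S standard) are returned alongside the
#' assemblies.
#'
#' @param cfg a [simConfig()] object.
#' @return list with elements `genomes` (named list of
#'   [GenomeAssembly-class]), `truth` ([SimTruth-class]) and `refs` (list of
#'   reference inputs: `core_proteins`, `core_lengths`, `marker_genes`,
#'   `hk_alleles`, `primers`, `standard_16s`, `nod_proteins`,
#'   `gene_truth` per-strain planted core-gene sequences).
#' @export
simulateComplex <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed)

  bp <- .build_chrom_blueprint(cfg)
  nod <- .build_nod_alleles()
  plasmid_bb <- lapply(seq_len(cfg$n_plasmids), function(i) .random_dna(cfg$plasmid_len))

  n_gs <- cfg$n_genospecies
  spg <- rep_len(cfg$strains_per_gs, n_gs)
  gs_names <- sprintf("gs%02d", seq_len(n_gs))

  draw <- function(rng) if (length(rng) == 2L) stats::runif(1L, rng[[1L]], rng[[2L]]) else rng
  d_between <- vapply(seq_len(n_gs), function(i) draw(cfg$between_gs_divergence), 0)
  d_within <- vapply(seq_len(n_gs), function(i) draw(cfg$within_gs_divergence), 0)

  # accessory pools: per genospecies
  acc_pool <- list()
  if (cfg$accessory_pool_per_gs > 0) {
    for (g in seq_len(n_gs)) {
      ids <- sprintf("%s_acc%03d", gs_names[[g]], seq_len(cfg$accessory_pool_per_gs))
      acc_pool[[gs_names[[g]]]] <- setNames(
        lapply(ids, function(i) .random_gene(cfg$accessory_gene_len)), ids)
    }
  }

  mut_segments <- function(segs, d, indel) {
    lapply(segs, function(s) { s$seq <- mutateSeq(s$seq, d, indel); s })
  }

  # per-genospecies ancestors (branch = pairwise/2)
  gs_anc <- list(); gs_plasmid <- list()
  for (g in seq_len(n_gs)) {
    br <- d_between[[g]] / 2
    gs_anc[[g]] <- mut_segments(bp$segments, br, cfg$indel_rate / 2)
    gs_plasmid[[g]] <- lapply(plasmid_bb, mutateSeq,
                              d = min(0.749, br * cfg$plasmid_rate_multiplier),
                              indel_rate = cfg$indel_rate / 2)
  }

  all_strains <- character(); strain_gs <- character()
  symb_levels <- c("viciae", "trifolii", "phaseoli", "none")
  sv_assign <- cfg$symbiovar_assignment
  genomes <- list()
  truth_comp <- list(); truth_acc <- list(); gene_truth <- list()
  hk_genes <- c("atpD", "gyrB", "recA")
  symb <- character()

  emit_strain <- function(strain, segs, plasmids, gs_label, sv, acc_genes, acc_ids) {
    chrom <- paste0(vapply(segs, function(s) s$seq, ""), collapse = "")
    # split chromosome into scaffolds at segment boundaries nearest to even cuts
    seg_len <- vapply(segs, function(s) nchar(s$seq), 0)
    ends <- cumsum(seg_len)
    nsc <- max(1L, cfg$n_chrom_scaffolds)
    cuts <- unique(vapply(seq_len(nsc - 1L), function(k) {
      target <- k * nchar(chrom) / nsc
      ends[[which.min(abs(ends - target))]]
    }, 0))
    bounds <- c(0, cuts, nchar(chrom))
    chrom_scafs <- vapply(seq_len(length(bounds) - 1L), function(i)
      substr(chrom, bounds[[i]] + 1L, bounds[[i + 1L]]), "")
    # plasmid scaffolds: conserved backbones, plus one accessory plasmid
    # carrying the strain's retained accessory genes and (for symbiotic
    # strains) the nod cassette
    plas_scafs <- unlist(plasmids)
    cargo <- character(0)
    if (length(acc_genes)) cargo <- c(cargo, unlist(acc_genes))
    if (sv != "none") cargo <- c(cargo, unlist(nod_strain(sv)))
    if (length(cargo)) plas_scafs <- c(plas_scafs, paste0(cargo, collapse = ""))
    scafs <- c(chrom_scafs, plas_scafs)
    labels <- c(rep("chromosomal", length(chrom_scafs)), rep("plasmid", length(plas_scafs)))
    ord <- sample(length(scafs))
    scafs <- scafs[ord]; labels <- labels[ord]
    names(scafs) <- sprintf("%s_s%d", strain, seq_along(scafs))
    genomes[[strain]] <<- genomeAssembly(strain, scafs,
                                         provenance = sprintf("simulated (seed %d)", cfg$seed))
    truth_comp[[strain]] <<- data.frame(strain = strain, scaffold = names(scafs),
                                        compartment = labels, stringsAsFactors = FALSE)
    truth_acc[[strain]] <<- acc_ids
    gene_truth[[strain]] <<- setNames(
      vapply(segs[vapply(segs, function(s) s$kind, "") == "core"], function(s) s$seq, ""),
      vapply(segs[vapply(segs, function(s) s$kind, "") == "core"], function(s) s$name, ""))
  }

  nod_strain <- function(sv) lapply(nod[[sv]], .mutate_coding, d = 0.005)

  k <- 0L
  for (g in seq_len(n_gs)) {
    for (s in seq_len(spg[[g]])) {
      k <- k + 1L
      strain <- sprintf("%s_t%02d", gs_names[[g]], s)
      brw <- d_within[[g]] / 2
      segs <- mut_segments(gs_anc[[g]], brw, cfg$indel_rate / 2)
      plas <- lapply(gs_plasmid[[g]], mutateSeq,
                     d = min(0.749, brw * cfg$plasmid_rate_multiplier),
                     indel_rate = cfg$indel_rate / 2)
      sv <- if (is.null(sv_assign)) symb_levels[[(k - 1L) %% 4L + 1L]]
            else rep_len(sv_assign, sum(spg))[[k]]
      # accessory retention
      acc_genes <- list(); acc_ids <- character()
      if (cfg$accessory_pool_per_gs > 0) {
        for (h in seq_len(n_gs)) {
          dd <- if (h == g) 0 else (d_between[[g]] + d_between[[h]]) / 2
          p <- cfg$accessory_retain_prob * exp(-cfg$accessory_share_decay * dd)
          keep <- stats::runif(cfg$accessory_pool_per_gs) < p
          ids <- names(acc_pool[[gs_names[[h]]]])[keep]
          # gene copies diverge along the host lineage (ancestral pool ->
          # genospecies branch -> strain branch)
          d_path <- d_between[[g]] / 2 + brw
          for (id in ids)
            acc_genes[[id]] <- .mutate_coding(acc_pool[[gs_names[[h]]]][[id]], d_path)
          acc_ids <- c(acc_ids, ids)
        }
      }
      all_strains <- c(all_strains, strain)
      strain_gs <- c(strain_gs, gs_names[[g]])
      symb[strain] <- sv
      emit_strain(strain, segs, plas, gs_names[[g]], sv, acc_genes, acc_ids)
    }
  }
  # isolates: deep independent lineages, each a singleton
  for (i in seq_len(cfg$n_isolates)) {
    strain <- sprintf("iso%02d", i)
    br <- cfg$isolate_divergence / 2
    segs <- mut_segments(bp$segments, br, cfg$indel_rate / 2)
    plas <- lapply(plasmid_bb, mutateSeq, d = min(0.749, br * cfg$plasmid_rate_multiplier),
                   indel_rate = cfg$indel_rate / 2)
    all_strains <- c(all_strains, strain)
    strain_gs <- c(strain_gs, strain) # its own label in truth
    symb[strain] <- "none"
    emit_strain(strain, segs, plas, strain, "none", list(), character())
  }
  if (cfg$outgroup) {
    strain <- "outgroup"
    br <- cfg$outgroup_divergence - mean(d_between) / 2 - mean(d_within) / 2
    br <- max(br, 0.001)
    segs <- mut_segments(bp$segments, br, cfg$indel_rate / 2)
    plas <- lapply(plasmid_bb, mutateSeq, d = min(0.749, br * cfg$plasmid_rate_multiplier),
                   indel_rate = cfg$indel_rate / 2)
    all_strains <- c(all_strains, strain)
    strain_gs <- c(strain_gs, strain)
    symb[strain] <- "none"
    emit_strain(strain, segs, plas, strain, "none", list(), character())
  }

  genospecies <- setNames(strain_gs, all_strains)

  # housekeeping-allele introgression: overwrite recipient's gene in place
  intro <- data.frame(recipient = character(), gene = character(),
                      donor_gs = character(), stringsAsFactors = FALSE)
  gs_hk_allele <- function(g, gene) {
    segs <- gs_anc[[g]]
    segs[[which(vapply(segs, function(s) s$name, "") == gene)]]$seq
  }
  if (cfg$n_introgressions > 0 && n_gs >= 2) {
    ingroup <- all_strains[genospecies[all_strains] %in% gs_names]
    rec <- sample(ingroup, cfg$n_introgressions,
                  replace = cfg$n_introgressions > length(ingroup))
    rec <- unique(rec)
    for (r in rec) {
      g_rec <- match(genospecies[[r]], gs_names)
      g_don <- sample(setdiff(seq_len(n_gs), g_rec), 1L)
      gene <- sample(hk_genes, 1L)
      donor_allele <- gs_hk_allele(g_don, gene)
      # locate the recipient's current allele by search and substitute
      gme <- genomes[[r]]
      hit <- nucleotideSearch(setNames(donor_allele, gene), gme, evalue_cutoff = 1e-5)
      if (is.null(hit)) next
      scafs <- as.character(scaffolds(gme))
      s <- scafs[[hit$scaffold]]
      repl <- if (hit$strand == "+") donor_allele else revComp(donor_allele)
      scafs[[hit$scaffold]] <- paste0(substr(s, 1L, hit$start),
                                      repl,
                                      substr(s, hit$end + 1L, nchar(s)))
      genomes[[r]] <- genomeAssembly(r, scafs, provenance = gme@provenance)
      intro <- rbind(intro, data.frame(recipient = r, gene = gene,
                                       donor_gs = gs_names[[g_don]],
                                       stringsAsFactors = FALSE))
    }
  }

  truth <- methods::new("SimTruth",
    genospecies = genospecies,
    compartments = do.call(rbind, truth_comp),
    symbiovar = symb[all_strains],
    introgressions = intro,
    accessory = truth_acc)

  core_segs <- bp$segments[vapply(bp$segments, function(s) s$kind, "") == "core"]
  core_names <- vapply(core_segs, function(s) s$name, "")
  core_nt <- setNames(vapply(core_segs, function(s) s$seq, ""), core_names)
  ord <- order(core_names)
  core_nt <- core_nt[ord]
  marker_segs <- bp$segments[vapply(bp$segments, function(s) s$kind, "") == "marker"]
  hk_alleles <- list()
  for (gene in hk_genes) {
    hk_alleles[[gene]] <- setNames(
      vapply(seq_len(n_gs), function(g) gs_hk_allele(g, gene), ""), gs_names)
  }
  std16 <- bp$segments[[which(vapply(bp$segments, function(s) s$kind, "") == "sixteens")]]$seq
  nod_prot <- list()
  for (sv in names(nod))
    for (gene in names(nod[[sv]]))
      nod_prot[[paste0(gene, "_", sv)]] <- sub("\\*$", "", translateDna(nod[[sv]][[gene]]))

  refs <- list(
    core_proteins = setNames(vapply(core_nt, function(s) sub("\\*$", "", translateDna(s)), ""),
                             names(core_nt)),
    core_lengths = setNames(rep(cfg$core_gene_len, length(core_nt)), names(core_nt)),
    core_nt = core_nt,
    marker_genes = setNames(vapply(marker_segs, function(s) s$seq, ""),
                            vapply(marker_segs, function(s) s$name, "")),
    hk_alleles = hk_alleles,
    primers = bp$primers,
    standard_16s = std16,
    nod_proteins = nod_prot,
    gene_truth = gene_truth)

  list(genomes = genomes, truth = truth, refs = refs, config = cfg)
}

#' Write / read simulation truth
#'
#' Truth is stored as a tab-separated strain table plus a JSON sidecar
#' (compartments, introgressions, accessory sets); the pair round-trips
#' losslessly.
#'
#' @param truth a [SimTruth-class].
#' @param path base path; writes `<path>.tsv` and `<path>.json`.
#' @return `path` invisibly ([writeTruth()]); a `SimTruth` ([readTruth()]).
#' @export
writeTruth <- function(truth, path) {
  df <- data.frame(strain = names(truth@genospecies),
                   genospecies = unname(truth@genospecies),
                   symbiovar = unname(truth@symbiovar[names(truth@genospecies)]),
                   stringsAsFactors = FALSE)
  write.table(df, paste0(path, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(compartments = truth@compartments,
               introgressions = truth@introgressions,
               accessory = truth@accessory)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  df <- read.table(paste0(path, ".tsv"), sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  bad <- setdiff(df$symbiovar, c("viciae", "trifolii", "phaseoli", "none"))
  if (length(bad)) stop("unknown symbiovar label: ", bad[[1L]])
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  comp <- as.data.frame(side$compartments, stringsAsFactors = FALSE)
  if (nrow(comp) && !all(comp$compartment %in% c("chromosomal", "plasmid")))
    stop("unknown compartment label in ", path, ".json")
  intro <- as.data.frame(side$introgressions, stringsAsFactors = FALSE)
  if (!nrow(intro))
    intro <- data.frame(recipient = character(), gene = character(),
                        donor_gs = character(), stringsAsFactors = FALSE)
  acc <- side$accessory
  acc <- lapply(acc, function(x) as.character(unlist(x)))
  methods::new("SimTruth",
    genospecies = setNames(df$genospecies, df$strain),
    compartments = comp,
    symbiovar = setNames(df$symbiovar, df$strain),
    introgressions = intro,
    accessory = acc[df$strain])
}

#' Write simulated genomes as one FASTA per strain
#'
#' @param genomes named list of [GenomeAssembly-class].
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
writeGenomesDir <- function(genomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in genomes)
    writeFasta(scaffolds(g), file.path(dir, paste0(strainId(g), ".fasta")))
  invisible(dir)
}
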