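# Shared simulated fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small 3-genospecies complex with one isolated strain; no accessory pool
sim_basic <- function() fixture("sim_basic", function() {
  simulateComplex(simConfig(
    n_genospecies = 3, strains_per_gs = 3, chrom_len = 40000,
    n_plasmids = 1, plasmid_len = 10000, n_core_genes = 12,
    core_gene_len = 600, n_chrom_markers = 6, marker_len = 450,
    within_gs_divergence = 0.01, between_gs_divergence = 0.06,
    n_isolates = 1, seed = 101))
})

ani_basic <- function() fixture("ani_basic", function() {
  aniMatrix(sim_basic()$genomes)
})

phylo_basic <- function() fixture("phylo_basic", function() {
  sim <- sim_basic()
  core <- coreGeneSet(sim$refs$core_proteins, sim$refs$core_lengths,
                      sim$refs$core_nt)
  corePhylogeny(sim$genomes, core)
})

# 2-genospecies complex with accessory pools, introgression and all four
# symbiovar labels; used by marker and accessory tests
sim_markers <- function() fixture("sim_markers", function() {
  simulateComplex(simConfig(
    n_genospecies = 2, strains_per_gs = 4, chrom_len = 30000,
    n_plasmids = 1, plasmid_len = 8000, n_core_genes = 8,
    core_gene_len = 600, n_chrom_markers = 5, marker_len = 450,
    accessory_pool_per_gs = 8, accessory_gene_len = 450,
    within_gs_divergence = 0.01, between_gs_divergence = 0.06,
    n_introgressions = 2, seed = 103))
})

# 5 genospecies x 6 strains plus two deep isolates: the genospecies
# recovery conditions (within-ANI ~99, between <= 95.5, isolates ~91)
sim_recovery <- function() fixture("sim_recovery", function() {
  simulateComplex(simConfig(
    n_genospecies = 5, strains_per_gs = 6, chrom_len = 40000,
    n_plasmids = 1, plasmid_len = 10000, n_core_genes = 12,
    core_gene_len = 600, n_chrom_markers = 6, marker_len = 450,
    within_gs_divergence = 0.01, between_gs_divergence = c(0.05, 0.07),
    n_isolates = 2, isolate_divergence = 0.11, seed = 201))
})

ani_recovery <- function() fixture("ani_recovery", function() {
  aniMatrix(sim_recovery()$genomes)
})

phylo_recovery <- function() fixture("phylo_recovery", function() {
  sim <- sim_recovery()
  core <- coreGeneSet(sim$refs$core_proteins, sim$refs$core_lengths,
                      sim$refs$core_nt)
  corePhylogeny(sim$genomes, core)
})

# 120 core genes (the 2 x 60 split-half design) over 5 genospecies
sim_phylo120 <- function() fixture("sim_phylo120", function() {
  simulateComplex(simConfig(
    n_genospecies = 5, strains_per_gs = 2, chrom_len = 100000,
    n_plasmids = 0, plasmid_len = 1, n_core_genes = 120,
    core_gene_len = 600, n_chrom_markers = 8, marker_len = 450,
    within_gs_divergence = 0.01, between_gs_divergence = c(0.05, 0.07),
    seed = 202))
})

# genospecies-specific accessory pools for the sharing-index pattern
sim_sharing <- function() fixture("sim_sharing", function() {
  simulateComplex(simConfig(
    n_genospecies = 3, strains_per_gs = 3, chrom_len = 30000,
    n_plasmids = 1, plasmid_len = 8000, n_core_genes = 8,
    core_gene_len = 600, n_chrom_markers = 5, marker_len = 450,
    accessory_pool_per_gs = 10, accessory_gene_len = 450,
    within_gs_divergence = 0.01, between_gs_divergence = 0.06,
    seed = 203))
})

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# a clean protein-coding gene (ATG ... TAA) of len_nt nucleotides
random_gene <- function(len_nt) genodelim:::.random_gene(len_nt)
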