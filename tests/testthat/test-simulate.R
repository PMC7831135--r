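test_that("mutateSeq matches binomial expectations and composes", {
  set.seed(5)
  s <- random_dna(100000)
  expect_identical(mutateSeq(s, 0), s)
  expect_error(mutateSeq(s, 0.8), "0.75")

  mism <- function(a, b) {
    mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  d <- 0.04
  m <- mutateSeq(s, d)
  sd3 <- 3 * sqrt(d * (1 - d) / nchar(s))
  expect_lt(abs(mism(s, m) - d), sd3)

  # two independent descendants at d = 0.02: expected pairwise mismatch
  # 2d(1-d) + d^2 * 2/3 (both mutated, different targets w.p. 2/3)
  d2 <- 0.02
  a <- mutateSeq(s, d2); b <- mutateSeq(s, d2)
  exp_p <- 2 * d2 * (1 - d2) + d2^2 * 2 / 3
  expect_lt(abs(mism(a, b) - exp_p), 3 * sqrt(exp_p * (1 - exp_p) / nchar(s)))
})

test_that("simulated divergence structure orders identities correctly", {
  sim <- simulateComplex(simConfig(
    n_genospecies = 2, strains_per_gs = 2, chrom_len = 20000, n_plasmids = 0,
    plasmid_len = 1, n_core_genes = 6, core_gene_len = 600,
    n_chrom_markers = 3, marker_len = 450,
    within_gs_divergence = 0.005, between_gs_divergence = 0.06, seed = 21))
  raw_id <- function(a, b) {
    # scaffold emission order is shuffled per strain; homologous scaffolds
    # are recovered by length (substitution-only: lengths are conserved)
    xs <- scaffolds(sim$genomes[[a]])
    ys <- scaffolds(sim$genomes[[b]])
    x <- paste(as.character(xs)[order(Biostrings::width(xs))], collapse = "")
    y <- paste(as.character(ys)[order(Biostrings::width(ys))], collapse = "")
    mean(strsplit(x, "")[[1]] == strsplit(y, "")[[1]])
  }
  # within-pair raw identity > between-pair raw identity
  g <- names(sim$genomes)
  within <- raw_id("gs01_t01", "gs01_t02")
  between <- raw_id("gs01_t01", "gs02_t01")
  expect_gt(within, between)
})

test_that("same seed gives byte-identical output, symbiovar none lacks nod genes", {
  cfg <- simConfig(n_genospecies = 2, strains_per_gs = 2, chrom_len = 15000,
                   n_plasmids = 1, plasmid_len = 6000, n_core_genes = 4,
                   core_gene_len = 600, n_chrom_markers = 3, marker_len = 450,
                   symbiovar_assignment = c("viciae", "none", "trifolii", "none"),
                   seed = 33)
  s1 <- simulateComplex(cfg)
  s2 <- simulateComplex(cfg)
  expect_identical(lapply(s1$genomes, function(g) as.character(scaffolds(g))),
                   lapply(s2$genomes, function(g) as.character(scaffolds(g))))
  expect_identical(truthGenospecies(s1$truth), truthGenospecies(s2$truth))

  # symbiovar "none": no nod cassette -> no translated hit for nodC
  nodc <- s1$refs$nod_proteins[["nodC_viciae"]]
  hit_none <- translatedSearch(c(nodC = nodc), s1$genomes[["gs01_t02"]],
                               evalue_cutoff = 1e-5)
  hit_vic <- translatedSearch(c(nodC = nodc), s1$genomes[["gs01_t01"]],
                              evalue_cutoff = 1e-5)
  expect_null(hit_none)
  expect_false(is.null(hit_vic))
})

test_that("truth tables round-trip through TSV + JSON", {
  sim <- sim_markers()
  base <- withr::local_tempfile()
  writeTruth(sim$truth, base)
  back <- readTruth(base)
  expect_identical(truthGenospecies(back), truthGenospecies(sim$truth))
  expect_identical(truthSymbiovar(back), truthSymbiovar(sim$truth))
  expect_equal(truthCompartments(back), truthCompartments(sim$truth),
               ignore_attr = TRUE)
  expect_equal(truthIntrogressions(back), truthIntrogressions(sim$truth),
               ignore_attr = TRUE)
  expect_identical(truthAccessory(back), truthAccessory(sim$truth))

  # corrupted label on read is an error
  tsv <- readLines(paste0(base, ".tsv"))
  tsv[2] <- sub("\t[a-z]+$", "\tmystery", tsv[2])
  writeLines(tsv, paste0(base, ".tsv"))
  expect_error(readTruth(base), "unknown symbiovar")
})

test_that("housekeeping alleles are closest to their own genospecies without introgression", {
  sim <- sim_basic()
  expect_equal(nrow(truthIntrogressions(sim$truth)), 0)
  refs <- sim$refs
  for (strain in c("gs01_t01", "gs02_t02", "gs03_t03")) {
    gs <- truthGenospecies(sim$truth)[[strain]]
    for (gene in c("atpD", "gyrB", "recA")) {
      alleles <- refs$hk_alleles[[gene]]
      hit <- nucleotideSearch(setNames(alleles[[gs]], gene),
                              sim$genomes[[strain]], evalue_cutoff = 1e-5)
      seq <- extendHit(hit, nchar(alleles[[gs]]), sim$genomes[[strain]])
      ids <- vapply(alleles, function(a)
        globalAlign(seq, a, type = "nt")$identity, 0)
      expect_equal(names(which.max(ids)), gs, info = paste(strain, gene))
    }
  }
})
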