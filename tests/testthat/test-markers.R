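test_that("16S extraction recovers planted copies and flags truncations", {
  sim <- sim_basic()
  std <- sim$refs$standard_16s
  x <- extract16S(sim$genomes[["gs01_t01"]], std)
  expect_false(is.null(x))
  expect_false(x$incomplete)
  expect_equal(nchar(x$seq), nchar(std))

  # genome without a 16S: nothing found
  set.seed(91)
  bare <- genomeAssembly("bare", c(s = random_dna(20000)))
  expect_null(extract16S(bare, std))

  # copy truncated at a contig edge: incomplete
  g <- genomeAssembly("tr", c(s = paste0(substr(std, 500, nchar(std)),
                                         random_dna(5000))))
  tx <- extract16S(g, std)
  expect_true(tx$incomplete)
})

test_that("16S profiles report variants in standard coordinates and round-trip", {
  set.seed(92)
  std <- random_dna(1500)
  # the standard itself: empty profile
  p0 <- profile16S(std, std)
  expect_equal(nrow(p0$substitutions), 0)
  expect_equal(nrow(p0$insertions), 0)
  expect_false(p0$ivs)

  # single substitution at position 1076
  v <- std
  old <- substr(v, 1076, 1076)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  substr(v, 1076, 1076) <- new
  p1 <- profile16S(v, std)
  expect_equal(p1$substitutions$position, 1076)
  expect_equal(p1$substitutions$standard, old)
  expect_equal(p1$substitutions$observed, new)
  expect_equal(applyProfile16S(p1, std), v)

  # 78-nt intervening sequence replacing the loop at positions 73-76
  ivs <- random_dna(78)
  v2 <- paste0(substr(std, 1, 72), ivs, substr(std, 77, 1500))
  p2 <- profile16S(v2, std)
  expect_true(p2$ivs)
  expect_equal(p2$ivs_length, 78)
  expect_equal(applyProfile16S(p2, std), v2)
})

test_that("haplotyping masks single-strain substitutions but not shared ones", {
  set.seed(93)
  std <- random_dna(1500)
  mk_var <- function(pos) {
    v <- std
    for (p in pos) {
      old <- substr(v, p, p)
      substr(v, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    v
  }
  profs <- list(
    s1 = profile16S(std, std),
    s2 = profile16S(mk_var(500), std),      # private SNV -> masked
    s3 = profile16S(mk_var(c(700, 900)), std), # shared variant pair
    s4 = profile16S(mk_var(c(700, 900)), std))
  hap <- catalogHaplotypes(profs)
  h <- setNames(hap$haplotype, hap$strain)
  expect_equal(h[["s1"]], h[["s2"]]) # private variant merged away
  expect_equal(h[["s3"]], h[["s4"]])
  expect_false(h[["s1"]] == h[["s3"]])
})

test_that("symbiovar calls match simulator truth, including the NodA-only rule", {
  sim <- sim_markers()
  truth <- truthSymbiovar(sim$truth)
  for (strain in names(sim$genomes)) {
    call <- assignSymbiovar(sim$genomes[[strain]], sim$refs$nod_proteins)
    expected <- if (truth[[strain]] == "none") "nonnodulating" else truth[[strain]]
    expect_equal(call$call, expected, info = strain)
  }

  # a genome carrying only nodA is recorded as non-nodulating
  set.seed(94)
  nodA_vic <- sim$refs$nod_proteins[["nodA_viciae"]]
  # re-derive a nucleotide sequence encoding the reference NodA protein
  nodA_nt <- paste0(vapply(strsplit(paste0(nodA_vic, "*"), "")[[1]], function(aa) {
    names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa][1]
  }, ""), collapse = "")
  g <- genomeAssembly("onlyA", c(s = paste0(random_dna(3000), nodA_nt,
                                            random_dna(3000))))
  call <- assignSymbiovar(g, sim$refs$nod_proteins)
  expect_equal(call$call, "nonnodulating")
  expect_equal(unname(call$genes[["nodA"]]), "viciae")
  expect_true(all(is.na(call$genes[c("nodD", "nodB", "nodC")])))
})

test_that("amplicon extraction trims primers, tolerates 2 mismatches, normalizes orientation", {
  set.seed(95)
  fwd <- random_dna(20); rev <- random_dna(20)
  interior <- random_dna(534)
  pp <- primerPair("atpD", fwd, rev, 534)
  gene <- paste0(random_dna(40), fwd, interior, revComp(rev), random_dna(40))
  expect_equal(extractAmplicon(gene, pp), interior)
  # reverse-oriented input gives the identical amplicon
  expect_equal(extractAmplicon(revComp(gene), pp), interior)
  # two mismatches in the forward primer are tolerated
  fwd2 <- fwd
  substr(fwd2, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(fwd, 3, 3))[1]
  substr(fwd2, 9, 9) <- setdiff(c("A", "C", "G", "T"), substr(fwd, 9, 9))[1]
  gene2 <- paste0(random_dna(40), fwd2, interior, revComp(rev), random_dna(40))
  expect_equal(extractAmplicon(gene2, pp), interior)
  # three mismatches are not
  substr(fwd2, 15, 15) <- setdiff(c("A", "C", "G", "T"), substr(fwd, 15, 15))[1]
  gene3 <- paste0(random_dna(40), fwd2, interior, revComp(rev), random_dna(40))
  expect_null(extractAmplicon(gene3, pp))
})

test_that("allele classification: exact, ambiguous, and novel calls", {
  set.seed(96)
  a_gsE <- random_dna(534)
  a_gsB <- mutateSeq(a_gsE, 0.05)
  refs <- c(gsE = a_gsE, gsB = a_gsB)
  expect_equal(classifyByAlleles(a_gsE, refs)$call, "gsE")
  # tie between two labels -> ambiguous
  refs2 <- c(gsE = a_gsE, gsB = a_gsE)
  expect_equal(classifyByAlleles(a_gsE, refs2)$call, "ambiguous")
  # nothing close -> novel
  expect_equal(classifyByAlleles(random_dna(534), refs)$call, "novel")
})

test_that("single-gene classification errs exactly on introgressed strains; multi-gene recovers", {
  sim <- sim_markers()
  truth <- truthGenospecies(sim$truth)
  intro <- truthIntrogressions(sim$truth)
  expect_gt(nrow(intro), 0)
  genes <- c("atpD", "gyrB", "recA")
  refs <- list()
  pps <- list()
  for (g in genes) {
    pp <- sim$refs$primers[[g]]
    pps[[g]] <- primerPair(pp$gene, pp$forward, pp$reverse, pp$informative_len)
    refs[[g]] <- vapply(sim$refs$hk_alleles[[g]], extractAmplicon,
                        "", primer_pair = pps[[g]])
  }
  get_amplicon <- function(strain, gene) {
    allele <- sim$refs$hk_alleles[[gene]][[truth[[strain]]]]
    hit <- nucleotideSearch(setNames(allele, gene), sim$genomes[[strain]],
                            evalue_cutoff = 1e-5)
    seq <- extendHit(hit, nchar(allele), sim$genomes[[strain]])
    extractAmplicon(seq, pps[[gene]])
  }
  for (strain in names(sim$genomes)) {
    per_gene <- list()
    for (g in genes) {
      amp <- get_amplicon(strain, g)
      per_gene[[g]] <- amp
      call <- classifyByAlleles(amp, refs[[g]])$call
      introgressed <- any(intro$recipient == strain & intro$gene == g)
      if (introgressed) {
        donor <- intro$donor_gs[intro$recipient == strain & intro$gene == g]
        expect_equal(call, donor, info = paste(strain, g))
      } else {
        expect_equal(call, truth[[strain]], info = paste(strain, g))
      }
    }
    multi <- classifyMultiGene(per_gene, refs)
    expect_equal(multi$call, truth[[strain]], info = strain)
  }
})
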