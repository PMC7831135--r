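test_that("core genes are recovered near-identical to the planted copies", {
  sim <- sim_basic()
  core <- coreGeneSet(sim$refs$core_proteins, sim$refs$core_lengths,
                      sim$refs$core_nt)
  strain <- "gs01_t01"
  got <- extractCoreGenes(sim$genomes[[strain]], core)
  planted <- sim$refs$gene_truth[[strain]]
  expect_false(any(is.na(got)))
  for (g in names(planted)) {
    id <- globalAlign(got[[g]], planted[[g]], type = "nt")$identity
    expect_gte(id, 0.99)
  }
})

test_that("a deleted gene is reported missing and excluded by filterComplete", {
  sim <- sim_basic()
  core <- coreGeneSet(sim$refs$core_proteins, sim$refs$core_lengths,
                      sim$refs$core_nt)
  g <- sim$genomes[["gs01_t01"]]
  # delete core001 by overwriting its region with random sequence
  hit <- translatedSearch(c(core001 = core$proteins[["core001"]]), g)
  scafs <- as.character(scaffolds(g))
  s <- scafs[[hit$scaffold]]
  scafs[[hit$scaffold]] <- paste0(substr(s, 1, hit$start),
                                  random_dna(hit$end - hit$start),
                                  substr(s, hit$end + 1, nchar(s)))
  g2 <- genomeAssembly("mut", scafs)
  got <- extractCoreGenes(g2, core)
  expect_true(is.na(got[["core001"]]))
  expect_equal(sum(is.na(got)), 1)

  maps <- list(full = extractCoreGenes(g, core), partial = got)
  expect_equal(filterComplete(maps), "full")
  expect_equal(filterComplete(maps, required = length(core$genes) - 1),
               c("full", "partial"))
})

test_that("anchor alignment projects onto reference coordinates", {
  ref <- random_gene(300)
  identical_seq <- ref
  deleted <- paste0(substr(ref, 1, 150), substr(ref, 154, 300)) # 3-nt deletion
  aln <- anchorAlign(c(a = identical_seq, b = deleted), ref)
  expect_equal(ncol(aln), 300)
  expect_true(all(aln["a", ] != "-"))
  expect_equal(sum(aln["b", ] == "-"), 3)
  # insertions relative to the reference are dropped
  inserted <- paste0(substr(ref, 1, 150), "AAAGGG", substr(ref, 151, 300))
  aln2 <- anchorAlign(c(a = inserted), ref)
  expect_equal(ncol(aln2), 300)
})

test_that("concatenation tracks spans and rejects inconsistent strains", {
  a1 <- matrix("A", 2, 300, dimnames = list(c("s1", "s2"), NULL))
  a2 <- matrix("C", 2, 450, dimnames = list(c("s1", "s2"), NULL))
  sm <- concatenateGenes(list(g1 = a1, g2 = a2))
  expect_equal(ncol(sm$matrix), 750)
  expect_equal(sm$spans$start, c(0, 300))
  expect_equal(sm$spans$end, c(300, 750))
  expect_error(concatenateGenes(list()), "empty gene list")
  a3 <- matrix("G", 1, 10, dimnames = list("s1", NULL))
  expect_error(concatenateGenes(list(g1 = a1, g2 = a3)), "missing from gene g2")
})

test_that("Jukes-Cantor distance matches the closed form and ape", {
  m <- rbind(s1 = rep(c("A", "C", "G", "T"), 25),
             s2 = rep(c("A", "C", "G", "T"), 25))
  expect_equal(unname(jcDistance(m)["s1", "s2"]), 0)
  # p = 0.10 -> d = 0.107326 (closed form)
  m2 <- m
  m2["s2", 1:10] <- c("C", "A", "T", "G", "C", "A", "T", "G", "C", "A")
  expect_equal(unname(jcDistance(m2)["s1", "s2"]), 0.107326, tolerance = 1e-5)
  # cross-check against ape::dist.dna on the same alignment
  bin <- ape::as.DNAbin(tolower(m2))
  expect_equal(unname(jcDistance(m2)["s1", "s2"]),
               unname(as.matrix(ape::dist.dna(bin, model = "JC69"))["s1", "s2"]),
               tolerance = 1e-9)
  # gaps-only overlap is an error
  m3 <- rbind(s1 = c("A", "-"), s2 = c("-", "C"))
  expect_error(jcDistance(m3), "no shared non-gap columns")
  # saturation is an error
  m4 <- rbind(s1 = rep("A", 100), s2 = rep("C", 100))
  expect_error(jcDistance(m4), "saturated")
})

test_that("neighbor joining solves the three-point case and recovers topology", {
  d <- matrix(c(0, 0.2, 0.5,
                0.2, 0, 0.5,
                0.5, 0.5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(0.1, 0.1, 0.4))

  # additive 4-taxon matrix from tree ((a:1,b:2):1,(c:3,d:4):1)
  gen <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):1);")
  dm <- ape::cophenetic.phylo(gen)
  tr4 <- njTree(dm)
  expect_equal(ape::dist.topo(ape::unroot(tr4), ape::unroot(gen)), 0,
               ignore_attr = TRUE)
  # distances are reproduced exactly on an additive matrix
  expect_equal(ape::cophenetic.phylo(tr4)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-9)
})

test_that("simulated genospecies are monophyletic in full and split-half trees", {
  sim <- sim_basic()
  ph <- phylo_basic()
  truth <- truthGenospecies(sim$truth)
  expect_true(all(checkMonophyly(ph$tree, truth)))

  core <- coreGeneSet(sim$refs$core_proteins, sim$refs$core_lengths,
                      sim$refs$core_nt)
  halves <- splitHalfTrees(sim$genomes, core, gene_maps = ph$gene_maps)
  expect_equal(sort(c(halves$genes_A, halves$genes_B)), sort(core$genes))
  expect_length(intersect(halves$genes_A, halves$genes_B), 0)
  expect_true(all(checkMonophyly(halves$tree_A, truth)))
  expect_true(all(checkMonophyly(halves$tree_B, truth)))
})

test_that("checkMonophyly flags a swapped strain", {
  tree <- ape::read.tree(text = "(((a1:1,a2:1):1,b1:2):1,((b2:1,b3:1):1,a3:2):1);")
  labs <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", b3 = "B")
  mono <- checkMonophyly(tree, labs)
  expect_false(mono[["A"]])
  expect_false(mono[["B"]])
  labs2 <- c(a1 = "A", a2 = "A", b1 = "solo")
  mono2 <- checkMonophyly(tree, labs2)
  expect_true(mono2[["A"]])
  expect_true(mono2[["solo"]])
})

test_that("gene bootstrap gives full support for well-separated clades", {
  sim <- sim_basic()
  ph <- phylo_basic()
  core <- coreGeneSet(sim$refs$core_proteins, sim$refs$core_lengths,
                      sim$refs$core_nt)
  alns <- list()
  for (g in core$genes) {
    seqs <- vapply(ph$included, function(s) ph$gene_maps[[s]][[g]], "")
    alns[[g]] <- anchorAlign(seqs, core$nt[[g]])
  }
  bt <- geneBootstrapSupport(alns, ph$tree, n = 25, seed = 9)
  labs <- as.numeric(bt$node.label)
  # genospecies nodes (deep, well-separated) must be at 100%
  truth <- truthGenospecies(sim$truth)
  for (gs in c("gs01", "gs02", "gs03")) {
    tips <- names(truth)[truth == gs]
    node <- ape::getMRCA(bt, tips)
    expect_equal(labs[node - length(bt$tip.label)], 100)
  }
})
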