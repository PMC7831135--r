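# build a symmetric ANI matrix from a default value plus overrides
ani_fixture <- function(strains, default, overrides = list()) {
  n <- length(strains)
  m <- matrix(default, n, n, dimnames = list(strains, strains))
  diag(m) <- 100
  for (ov in overrides) m[ov[[1]], ov[[2]]] <- m[ov[[2]], ov[[1]]] <- ov[[3]]
  m
}

test_that("single-linkage components follow the threshold", {
  m <- ani_fixture(c("a", "b", "c", "d"), 94,
                   list(list("a", "b", 97), list("c", "d", 98)))
  expect_equal(linkageComponents(m, 96), list(c("a", "b"), c("c", "d")))

  # chaining: a-b 97, b-c 96.5, a-c 95.5 -> one component
  m2 <- ani_fixture(c("a", "b", "c"), 95.5,
                    list(list("a", "b", 97), list("b", "c", 96.5)))
  expect_equal(linkageComponents(m2, 96), list(c("a", "b", "c")))

  # all below threshold: singletons
  m3 <- ani_fixture(c("a", "b", "c"), 95)
  expect_equal(linkageComponents(m3, 96), list("a", "b", "c"))

  # undefined entries are no edge
  m4 <- ani_fixture(c("a", "b"), NA_real_)
  expect_equal(linkageComponents(m4, 96), list("a", "b"))
})

test_that("detectGap returns the largest empty interval in the window", {
  strains <- c("ref", "v1", "v2", "v3", "v4", "v5")
  m <- ani_fixture(strains, 90)
  m["ref", c("v1", "v2", "v3", "v4", "v5")] <-
    m[c("v1", "v2", "v3", "v4", "v5"), "ref"] <- c(98.1, 97.4, 95.0, 94.2, 93.0)
  g <- detectGap("ref", m, c(94.5, 97.5))
  expect_equal(unname(g), c(95.0, 97.4))

  # all values above the window: no gap
  m2 <- ani_fixture(c("ref", "x", "y"), 98)
  expect_null(detectGap("ref", m2, c(94.5, 97.5)))
})

test_that("medoid representative maximizes mean ANI, ties break lexicographically", {
  m <- ani_fixture(c("a", "b", "c"), 97,
                   list(list("b", "a", 99), list("b", "c", 99)))
  expect_equal(selectRepresentative(c("a", "b", "c"), m), "b")
  expect_equal(selectRepresentative("z", m), "z")
  # exact tie -> smaller id
  m2 <- ani_fixture(c("b", "a"), 98)
  expect_equal(selectRepresentative(c("b", "a"), m2), "a")
})

test_that("adjusted Rand index matches the contingency formula and mclust", {
  p1 <- setNames(c("x", "x", "x", "y", "y", "y"), paste0("s", 1:6))
  expect_equal(comparePartitions(p1, p1)$ari, 1)

  singletons <- setNames(paste0("c", 1:6), paste0("s", 1:6))
  lumped <- setNames(rep("one", 6), paste0("s", 1:6))
  expect_equal(comparePartitions(singletons, lumped)$ari, 0)

  p2 <- setNames(c("u", "u", "v", "v", "v", "u"), paste0("s", 1:6))
  got <- comparePartitions(p1, p2)$ari
  # independent oracle
  expect_equal(got, mclust::adjustedRandIndex(p1, p2))
  mapping <- comparePartitions(p1, p2)$mapping
  expect_true(all(mapping$n > 0))
})

test_that("compact subcluster with bridges is split; bridges follow the tree", {
  # X = x1..x4 all >= 98 (compact); Y = y1..y3 at 97 within; cross pairs 95
  # except the bridge y1-x1 at 96.2
  strains <- c(paste0("x", 1:4), paste0("y", 1:3))
  ov <- list()
  for (i in 1:4) for (j in 1:4) if (i < j)
    ov[[length(ov) + 1]] <- list(paste0("x", i), paste0("x", j), 98.5)
  for (i in 1:3) for (j in 1:3) if (i < j)
    ov[[length(ov) + 1]] <- list(paste0("y", i), paste0("y", j), 97)
  ov[[length(ov) + 1]] <- list("y1", "x1", 96.2)
  m <- ani_fixture(strains, 95, ov)
  tree <- ape::read.tree(text = "(((x1:1,x2:1):1,(x3:1,x4:1):1):2,((y1:1,y2:1):1,y3:2):2);")
  part <- refineComponents(linkageComponents(m, 96), m, tree, partitionParams())
  labs <- gsLabels(part)
  expect_equal(length(unique(labs)), 2)
  expect_equal(length(unique(labs[paste0("x", 1:4)])), 1)
  expect_equal(length(unique(labs[paste0("y", 1:3)])), 1)
  # the bridge stays with its tree neighbours
  expect_equal(unname(labs[["y1"]]), unname(labs[["y2"]]))
  expect_false(labs[["y1"]] == labs[["x1"]])
})

test_that("fully compact components are never split; singletons are unplaced", {
  strains <- c("a", "b", "c", "d", "solo")
  ov <- list()
  for (i in 1:4) for (j in 1:4) if (i < j)
    ov[[length(ov) + 1]] <- list(strains[i], strains[j], 98.5)
  m <- ani_fixture(strains, 90, ov)
  tree <- ape::read.tree(text = "(((a:1,b:1):1,(c:1,d:1):1):1,solo:3);")
  part <- refineComponents(linkageComponents(m, 96), m, tree, partitionParams())
  expect_equal(length(unique(gsLabels(part))), 1)
  expect_equal(sort(names(gsLabels(part))), c("a", "b", "c", "d"))
  expect_equal(unplacedStrains(part), "solo")

  # strain missing from the tree is an error
  tree2 <- ape::drop.tip(tree, "a")
  expect_error(refineComponents(linkageComponents(m, 96), m, tree2,
                                partitionParams()), "missing from tree: a")
})

test_that("raising the species threshold never merges clusters", {
  am <- ani_basic()
  tree <- phylo_basic()$tree
  labels_at <- function(thr) {
    part <- delineateGenospecies(am$matrix, tree,
                                 partitionParams(species_threshold = thr,
                                                 compactness_threshold = thr + 2,
                                                 gap_window = c(thr - 1.5, thr + 1.5)))
    gsLabels(part)
  }
  l96 <- labels_at(96)
  l97 <- labels_at(97)
  # every 97-cluster is contained in a single 96-cluster
  for (lab in unique(l97)) {
    members <- names(l97)[l97 == lab]
    expect_equal(length(unique(l96[members])), 1)
  }
})

test_that("delineation recovers simulated genospecies and gap bounds straddle 96", {
  sim <- sim_basic()
  am <- ani_basic()
  part <- delineateGenospecies(am$matrix, phylo_basic()$tree)
  truth <- truthGenospecies(sim$truth)
  expect_equal(comparePartitions(gsLabels(part), truth)$ari, 1)
  expect_equal(unplacedStrains(part), "iso01")
  gaps <- gapBounds(part)
  expect_true(all(gaps$gap_low < 96 & gaps$gap_high > 96))
})

test_that("classifyStrain assigns held-out strains and rejects outliers", {
  sim <- sim_basic()
  am <- ani_basic()
  tree <- phylo_basic()$tree
  held <- "gs02_t03"
  keep <- setdiff(rownames(am$matrix), held)
  part <- delineateGenospecies(am$matrix[keep, keep],
                               ape::drop.tip(tree, held))
  lab <- classifyStrain(sim$genomes[[held]], part, sim$genomes)
  truth_lab <- unique(gsLabels(part)[names(gsLabels(part)) %in%
    setdiff(names(truthGenospecies(sim$truth))[
      truthGenospecies(sim$truth) == "gs02"], held)])
  expect_equal(lab, truth_lab)

  # the isolate is far from every representative
  expect_equal(classifyStrain(sim$genomes[["iso01"]], part, sim$genomes),
               "unplaced")
  # a representative classifies to its own label
  rep1 <- representatives(part)[[1]]
  expect_equal(classifyStrain(sim$genomes[[rep1]], part, sim$genomes),
               names(representatives(part))[[1]])
})
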