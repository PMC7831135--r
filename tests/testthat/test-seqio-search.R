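test_that("FASTA reading joins wrapped lines, normalizes case, round-trips", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a desc", "AC", "gt", ">b", "GGGG"), p)
  x <- readFasta(p)
  expect_equal(as.character(x), c(a = "ACGT", b = "GGGG"))

  # round trip through writeFasta with wrapping
  p2 <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(setNames(c("ACGT", "GGGG"), c("a", "b")), p2, wrap = 3)
  expect_equal(as.character(readFasta(p2)), c(a = "ACGT", b = "GGGG"))
})

test_that("FASTA reader rejects duplicates and empty files", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "GG"), p)
  expect_error(readFasta(p), "duplicate id a")
  p2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), p2)
  expect_error(readFasta(p2), "empty")
})

test_that("six-frame translation follows the standard code", {
  expect_equal(sixFrameTranslate("ATGGCC")[["+1"]], "MA")
  # reverse complement of TTACAT is ATGTAA -> M*
  expect_equal(sixFrameTranslate("TTACAT")[["-1"]], "M*")
  # trailing partial codon dropped
  expect_equal(sixFrameTranslate("ATGG")[["+1"]], "M")
  # non-IUPAC translates as X
  expect_equal(translateDna("NNNATG"), "XM")
})

test_that("local alignment matches examples and an independent oracle", {
  expect_equal(localAlign("ACGT", "ACGT")$score, 4)
  expect_equal(localAlign("ACGT", "ACGT")$identity, 1.0)
  expect_equal(localAlign("ACGT", "AGGT")$identity, 0.75)
  # disjoint alphabets: the optimum is the empty alignment
  expect_equal(localAlign("AAAA", "CCCC")$score, 0)

  # oracle: Biostrings Smith-Waterman with the identical scoring scheme,
  # over random short pairs on a 2-letter alphabet
  set.seed(42)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (k in 1:40) {
    a <- paste(sample(c("A", "C"), sample(2:8, 1), replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C"), sample(2:8, 1), replace = TRUE), collapse = "")
    ours <- localAlign(a, b)$score
    ref <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                         substitutionMatrix = submat,
                                         gapOpening = 5, gapExtension = 2,
                                         scoreOnly = TRUE)
    expect_equal(ours, max(ref, 0), info = paste(a, b))
  }
})

test_that("protein local alignment agrees with BLOSUM62 oracle", {
  set.seed(7)
  data(BLOSUM62, package = "Biostrings", envir = environment())
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (k in 1:20) {
    a <- paste(sample(aa, sample(5:12, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(5:12, 1), replace = TRUE), collapse = "")
    ours <- localAlign(a, b, type = "aa")$score
    ref <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                         substitutionMatrix = BLOSUM62,
                                         gapOpening = 11, gapExtension = 1,
                                         scoreOnly = TRUE)
    expect_equal(ours, max(ref, 0), info = paste(a, b))
  }
})

test_that("translated search recovers planted ORFs at exact coordinates", {
  set.seed(11)
  backbone <- random_dna(4000)
  for (k in 1:12) {
    orf <- random_gene(300)
    at <- sample(500:3000, 1)
    strand <- sample(c("+", "-"), 1)
    ins <- if (strand == "+") orf else revComp(orf)
    g <- genomeAssembly("s", c(sc = paste0(substr(backbone, 1, at),
                                           ins,
                                           substr(backbone, at + 1, 4000))))
    hit <- translatedSearch(c(q = translateDna(orf)), g)
    expect_equal(hit$start, at)
    expect_equal(hit$end, at + 300)
    expect_equal(hit$strand, strand)
    expect_equal(hit$identity, 1.0)
  }
})

test_that("searches return nothing on unrelated random sequence", {
  set.seed(13)
  q <- random_gene(300)
  misses_t <- 0; misses_n <- 0
  for (k in 1:20) {
    g <- genomeAssembly("s", c(sc = random_dna(20000)))
    if (is.null(translatedSearch(c(q = translateDna(q)), g))) misses_t <- misses_t + 1
    if (is.null(nucleotideSearch(c(q = q), g))) misses_n <- misses_n + 1
  }
  expect_equal(misses_t, 20)
  expect_equal(misses_n, 20)
})

test_that("nucleotide search applies the documented tie-break", {
  set.seed(17)
  q <- random_dna(500)
  pad <- random_dna(1000)
  # identical copies on two scaffolds: lexicographically smaller wins
  g <- genomeAssembly("s", c(sB = paste0(pad, q), sA = paste0(pad, q)))
  hit <- nucleotideSearch(c(q = q), g)
  expect_equal(hit$scaffold, "sA")
  expect_equal(hit$start, 1000)
  # search is deterministic
  hit2 <- nucleotideSearch(c(q = q), g)
  expect_identical(hit, hit2)
})

test_that("extendHit extends symmetrically, truncates at contig ends", {
  g <- genomeAssembly("s", c(sc = paste(rep("ACGT", 250), collapse = "")))
  hit <- data.frame(query = "q", scaffold = "sc", start = 100L, end = 400L,
                    strand = "+", frame = 1L, score = 1, evalue = 0,
                    identity = 1)
  # expected == span: unchanged
  expect_equal(nchar(extendHit(hit, 300, g)), 300)
  expect_equal(extendHit(hit, 300, g),
               substr(as.character(scaffolds(g)[[1]]), 101, 400))
  # symmetric extension
  expect_equal(extendHit(hit, 320, g),
               substr(as.character(scaffolds(g)[[1]]), 91, 410))
  # left truncation: deficit not re-added on the right
  hit2 <- hit; hit2$start <- 10L; hit2$end <- 310L
  expect_equal(extendHit(hit2, 340, g),
               substr(as.character(scaffolds(g)[[1]]), 1, 330))
  expect_equal(nchar(extendHit(hit2, 340, g)), 330)
  # minus strand: reverse complement of the extracted window
  hit3 <- hit; hit3$strand <- "-"
  expect_equal(extendHit(hit3, 300, g),
               revComp(substr(as.character(scaffolds(g)[[1]]), 101, 400)))
  # expected shorter than span: warning, span returned
  expect_warning(out <- extendHit(hit, 200, g), "unextended")
  expect_equal(nchar(out), 300)
})
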