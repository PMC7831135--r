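#' @include genodelim-package.R
NULL

#' GenomeAssembly: one strain's genome assembly
#'
#' A lightweight container for a bacterial genome assembly: a strain
#' identifier, the scaffold sequences as a [Biostrings::DNAStringSet], and a
#' free-text provenance note (file of origin, simulator seed, ...).
#'
#' @slot strain single character, non-empty, the strain identifier.
#' @slot scaffolds a `DNAStringSet` with unique, non-empty names.
#' @slot provenance single character.
#' @export
setClass("GenomeAssembly",
  representation(strain = "character", scaffolds = "ANY", provenance = "character"),
  prototype(provenance = ""))

setValidity("GenomeAssembly", function(object) {
  msg <- character()
  if (length(object@strain) != 1L || !nzchar(object@strain))
    msg <- c(msg, "strain must be a single non-empty string")
  if (!methods::is(object@scaffolds, "DNAStringSet"))
    msg <- c(msg, "scaffolds must be a DNAStringSet")
  else {
    nm <- names(object@scaffolds)
    if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
      msg <- c(msg, "scaffold names must be unique and non-empty")
    if (length(object@scaffolds) == 0L)
      msg <- c(msg, "assembly has no scaffolds")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeAssembly
#'
#' @param strain strain identifier.
#' @param scaffolds named `DNAStringSet` (or named character vector of
#'   nucleotide sequences, which is coerced).
#' @param provenance optional free-text provenance.
#' @return a [GenomeAssembly-class] object.
#' @examples
#' g <- genomeAssembly("s1", c(sc1 = "ACGTACGT"))
#' strainId(g)
#' @export
genomeAssembly <- function(strain, scaffolds, provenance = "") {
  if (is.character(scaffolds))
    scaffolds <- Biostrings::DNAStringSet(toupper(scaffolds))
  methods::new("GenomeAssembly", strain = as.character(strain),
               scaffolds = scaffolds, provenance = as.character(provenance))
}

#' @describeIn GenomeAssembly-class strain identifier accessor
#' @param x,object a `GenomeAssembly`
#' @export
strainId <- function(x) x@strain

#' @describeIn GenomeAssembly-class scaffold sequences accessor
#' @export
scaffolds <- function(x) x@scaffolds

#' @describeIn GenomeAssembly-class total assembly length in nucleotides
#' @export
assemblyLength <- function(x) sum(Biostrings::width(x@scaffolds))

setMethod("show", "GenomeAssembly", function(object) {
  cat("GenomeAssembly", object@strain, "-", length(object@scaffolds),
      "scaffold(s),", sum(Biostrings::width(object@scaffolds)), "nt\n")
})

#' SimTruth: ground truth for a simulated species complex
#'
#' Ground-truth labels emitted by [simulateComplex()]: the genospecies of
#' every strain, the compartment (chromosomal/plasmid) of every scaffold,
#' per-strain symbiovar, housekeeping-allele introgression events, and
#' per-strain accessory gene complements.
#'
#' @slot genospecies named character, strain -> genospecies label.
#' @slot compartments data.frame with columns strain, scaffold, compartment.
#' @slot symbiovar named character, strain -> viciae/trifolii/phaseoli/none.
#' @slot introgressions data.frame with columns recipient, gene, donor_gs.
#' @slot accessory named list, strain -> character vector of accessory gene ids.
#' @export
setClass("SimTruth",
  representation(genospecies = "character", compartments = "data.frame",
                 symbiovar = "character", introgressions = "data.frame",
                 accessory = "list"))

setValidity("SimTruth", function(object) {
  msg <- character()
  if (is.null(names(object@genospecies)))
    msg <- c(msg, "genospecies must be a named character vector")
  need <- c("strain", "scaffold", "compartment")
  if (!all(need %in% names(object@compartments)))
    msg <- c(msg, "compartments must have columns strain, scaffold, compartment")
  else if (!all(object@compartments$compartment %in% c("chromosomal", "plasmid")))
    msg <- c(msg, "compartment labels must be 'chromosomal' or 'plasmid'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", length(object@genospecies), "strains,",
      length(unique(object@genospecies)), "genospecies,",
      nrow(object@introgressions), "introgression event(s)\n")
})

#' @describeIn SimTruth-class strain -> genospecies labels
#' @param x a `SimTruth`
#' @export
truthGenospecies <- function(x) x@genospecies

#' @describeIn SimTruth-class scaffold compartment table
#' @export
truthCompartments <- function(x) x@compartments

#' @describeIn SimTruth-class strain -> symbiovar labels
#' @export
truthSymbiovar <- function(x) x@symbiovar

#' @describeIn SimTruth-class introgression events
#' @export
truthIntrogressions <- function(x) x@introgressions

#' @describeIn SimTruth-class per-strain accessory gene id sets
#' @export
truthAccessory <- function(x) x@accessory

#' GenospeciesPartition: a delineation of strains into genospecies
#'
#' The result of genospecies delineation: placed strains carry a genospecies
#' label; each label has a medoid representative; strains that could not be
#' placed (singletons, strains expelled by refinement) are listed as
#' unplaced; per-label ANI gap bounds document the boundary.
#'
#' @slot labels named character, placed strain -> genospecies label.
#' @slot representatives named character, label -> representative strain.
#' @slot unplaced character vector of unplaced strain ids.
#' @slot gaps data.frame with columns label, gap_low, gap_high (percent ANI).
#' @export
setClass("GenospeciesPartition",
  representation(labels = "character", representatives = "character",
                 unplaced = "character", gaps = "data.frame"),
  prototype(gaps = data.frame(label = character(), gap_low = numeric(),
                              gap_high = numeric())))

setValidity("GenospeciesPartition", function(object) {
  msg <- character()
  if (length(object@labels) && is.null(names(object@labels)))
    msg <- c(msg, "labels must be named by strain")
  if (length(intersect(names(object@labels), object@unplaced)))
    msg <- c(msg, "a strain cannot be both placed and unplaced")
  for (lab in names(object@representatives)) {
    rep <- object@representatives[[lab]]
    if (!rep %in% names(object@labels)[object@labels == lab])
      msg <- c(msg, sprintf("representative %s does not belong to label %s", rep, lab))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GenospeciesPartition", function(object) {
  cat("GenospeciesPartition:", length(unique(object@labels)), "genospecies,",
      length(object@labels), "placed strains,",
      length(object@unplaced), "unplaced\n")
})

#' @describeIn GenospeciesPartition-class strain -> label mapping
#' @param x a `GenospeciesPartition`
#' @export
gsLabels <- function(x) x@labels

#' @describeIn GenospeciesPartition-class label -> representative strain
#' @export
representatives <- function(x) x@representatives

#' @describeIn GenospeciesPartition-class unplaced strain ids
#' @export
unplacedStrains <- function(x) x@unplaced

#' @describeIn GenospeciesPartition-class per-label ANI gap bounds
#' @export
gapBounds <- function(x) x@gaps

#' OrthogroupTable: per-genome orthogroup copy counts
#'
#' An orthogroup-by-genome copy-count matrix after the copy-number filters:
#' orthogroups with more than two copies in any one genome are excluded, as
#' are orthogroups present as a single copy in a single genome only.
#'
#' @slot counts integer matrix, orthogroups x genomes.
#' @export
setClass("OrthogroupTable", representation(counts = "matrix"))

setValidity("OrthogroupTable", function(object) {
  m <- object@counts
  msg <- character()
  if (any(m < 0)) msg <- c(msg, "copy counts must be >= 0")
  if (nrow(m) > 0) {
    if (any(apply(m, 1, max) > 2))
      msg <- c(msg, "orthogroup with more than two copies in one genome")
    singleton <- rowSums(m > 0) == 1L & rowSums(m) == 1L
    if (any(singleton))
      msg <- c(msg, "orthogroup present as single copy in a single genome")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "OrthogroupTable", function(object) {
  cat("OrthogroupTable:", nrow(object@counts), "orthogroups x",
      ncol(object@counts), "genomes\n")
})

#' @describeIn OrthogroupTable-class the copy-count matrix
#' @param x an `OrthogroupTable`
#' @export
orthogroupCounts <- function(x) x@counts
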