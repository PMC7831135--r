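#' @include corephylo.R
NULL

#' Classify scaffolds into chromosomal and plasmid compartments
#'
#' Each chromosomal marker gene contributes at most one hit per genome
#' (its single best nucleotide-search hit). A scaffold is chromosomal iff
#' it carries at least `min_markers` marker best-hits; all other scaffolds
#' are plasmid. `min_markers = 5` is the stringent variant.
#'
#' @param genome a [GenomeAssembly-class].
#' @param marker_genes named character vector of marker nucleotide
#'   sequences.
#' @param min_markers minimum marker best-hits for a chromosomal call
#'   (default 1).
#' @param evalue E-value cutoff (default `1e-10`).
#' @return data.frame with columns strain, scaffold, compartment,
#'   marker_count, length, fraction; one row per scaffold, fractions
#'   summing to 1.
#' @export
classifyScaffolds <- function(genome, marker_genes, min_markers = 1L,
                              evalue = 1e-10) {
  stopifnot(length(marker_genes) > 0)
  scafs <- scaffolds(genome)
  counts <- setNames(integer(length(scafs)), names(scafs))
  any_hit <- FALSE
  for (g in names(marker_genes)) {
    hit <- nucleotideSearch(setNames(marker_genes[[g]], g), genome,
                            evalue_cutoff = evalue)
    if (is.null(hit)) next
    any_hit <- TRUE
    counts[[hit$scaffold]] <- counts[[hit$scaffold]] + 1L
  }
  if (!any_hit)
    warning("no marker hits in genome ", strainId(genome),
            "; all scaffolds called plasmid")
  lens <- Biostrings::width(scafs)
  data.frame(strain = strainId(genome), scaffold = names(scafs),
             compartment = ifelse(counts >= min_markers, "chromosomal", "plasmid"),
             marker_count = unname(counts), length = lens,
             fraction = lens / sum(lens), stringsAsFactors = FALSE,
             row.names = NULL)
}

# assemble the sub-genome of one compartment (possibly empty)
.compartment_genome <- function(genome, calls, label) {
  keep <- calls$scaffold[calls$compartment == label]
  scafs <- scaffolds(genome)[keep]
  if (!length(scafs)) return(NULL)
  genomeAssembly(strainId(genome), scafs, provenance = label)
}

#' Per-compartment ANI between two genomes
#'
#' Runs directed fragment ANI on the matching compartments only
#' (chromosomal vs chromosomal, plasmid vs plasmid). A compartment empty
#' in either genome yields an undefined record.
#'
#' @param genome_a,genome_b [GenomeAssembly-class] objects.
#' @param calls_a,calls_b their [classifyScaffolds()] outputs.
#' @param params an [aniParams()] object.
#' @return data.frame with two rows (compartment chromosomal/plasmid) in
#'   the [aniPair()] dialect plus a `compartment` column.
#' @export
compartmentAni <- function(genome_a, genome_b, calls_a, calls_b,
                           params = aniParams()) {
  out <- list()
  for (label in c("chromosomal", "plasmid")) {
    ga <- .compartment_genome(genome_a, calls_a, label)
    gb <- .compartment_genome(genome_b, calls_b, label)
    rec <- if (is.null(ga) || is.null(gb))
      data.frame(query = strainId(genome_a), reference = strainId(genome_b),
                 ani = NA_real_, fragments_total = 0L, fragments_mapped = 0L,
                 shared_fraction = NA_real_, stringsAsFactors = FALSE)
    else aniPair(ga, gb, params)
    rec$compartment <- label
    out[[label]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
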