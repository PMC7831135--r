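#' @include classes.R
NULL

#' Read a FASTA file
#'
#' Reads a (nucleotide or protein) FASTA file into an `XStringSet`.
#' Sequence lines are concatenated and case-normalized to upper case; the
#' record id is the header token up to the first whitespace, the remainder
#' is kept as the description in `names()` metadata. Duplicate ids and empty
#' files are errors.
#'
#' @param path path to a FASTA file.
#' @param type `"nt"` (DNA, default) or `"aa"` (protein).
#' @return a [Biostrings::DNAStringSet] or [Biostrings::AAStringSet] named
#'   by record id.
#' @export
readFasta <- function(path, type = c("nt", "aa")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[[1L]]) stop("not a FASTA file (missing '>' header): ", path)
  grp <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id ", dup[[1L]], " in ", path)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, "", collapse = "")
  if (length(seqs) != length(ids) || any(!nzchar(seqs)))
    stop("FASTA record with empty sequence in ", path)
  seqs <- toupper(gsub("\\s", "", seqs))
  names(seqs) <- ids
  out <- if (type == "nt") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  out
}

#' Write sequences to FASTA
#'
#' @param x named `XStringSet` or named character vector.
#' @param path output path.
#' @param wrap line width (default 80).
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path, wrap = 80L) {
  if (is.character(x)) {
    stopifnot(!is.null(names(x)))
    seqs <- x
  } else {
    seqs <- as.character(x)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[[i]]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a directory of genome FASTA files
#'
#' One multi-FASTA per strain; the strain id is the file name without its
#' `.fa`/`.fasta`/`.fna` extension.
#'
#' @param dir directory containing FASTA files.
#' @return named list of [GenomeAssembly-class] objects.
#' @export
readGenomesDir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE))
  if (!length(files)) stop("no FASTA files in ", dir)
  out <- lapply(files, function(f) {
    strain <- sub("\\.(fa|fasta|fna)$", "", basename(f))
    genomeAssembly(strain, readFasta(f, "nt"), provenance = f)
  })
  names(out) <- vapply(out, strainId, "")
  out
}

#' Reverse complement
#' @param seq nucleotide string.
#' @return reverse-complemented string.
#' @export
revComp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a nucleotide string
#'
#' Standard (bacterial) genetic code; stops rendered as `*`; trailing
#' partial codon dropped; codons containing non-ACGT characters translate
#' to `X`.
#'
#' @param dna nucleotide string.
#' @return amino-acid string.
#' @export
translateDna <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  dna <- substr(toupper(dna), 1L, 3L * n)
  codons <- substring(dna, seq.int(1L, by = 3L, length.out = n),
                      seq.int(3L, by = 3L, length.out = n))
  aa <- .GENETIC_CODE_VEC[codons]
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

.GENETIC_CODE_VEC <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames: frames
#' `+1..+3` on the forward strand, `-1..-3` on the reverse complement.
#'
#' @param dna nucleotide string, length >= 3.
#' @return named character vector of six amino-acid strings
#'   (`"+1","+2","+3","-1","-2","-3"`).
#' @examples
#' sixFrameTranslate("ATGGCC")[["+1"]]  # "MA"
#' @export
sixFrameTranslate <- function(dna) {
  if (nchar(dna) < 3L) stop("sequence shorter than one codon")
  rc <- revComp(dna)
  out <- c(
    "+1" = translateDna(dna),
    "+2" = translateDna(substr(dna, 2L, nchar(dna))),
    "+3" = translateDna(substr(dna, 3L, nchar(dna))),
    "-1" = translateDna(rc),
    "-2" = translateDna(substr(rc, 2L, nchar(rc))),
    "-3" = translateDna(substr(rc, 3L, nchar(rc))))
  out
}
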