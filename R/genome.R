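#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet reverseComplement GENETIC_CODE
#' @importFrom stats rbinom runif rmultinom setNames
#' @importFrom utils write.table read.delim packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reference plastome object
#'
#' Wraps a single circular-plastome nucleotide sequence together with its
#' maximal homopolymer runs (stretches of identical bases), which are needed
#' to mask editing-like artifacts caused by sequencing slippage.
#'
#' @param sequence Character scalar over A/C/G/T (upper- or lower-case).
#' @param name Sequence name used in FASTA/GFF3/SAM headers.
#' @param homopolymer_min_run Minimum run length recorded as a homopolymer.
#' @return An object of class `plastome`: a list with elements `name`,
#'   `sequence`, `length` and `homopolymer` (data frame with columns
#'   `start`, `end`, `base`; 1-based closed intervals).
#' @export
plastome <- function(sequence, name = "plastome", homopolymer_min_run = 6L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence))
    stop("plastome sequence must contain only A/C/G/T")
  structure(
    list(
      name = as.character(name),
      sequence = sequence,
      length = nchar(sequence),
      homopolymer = find_homopolymer_runs(sequence, homopolymer_min_run)
    ),
    class = "plastome"
  )
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("<plastome> %s: %d bp, %d homopolymer run(s) >= %s bp\n",
              x$name, x$length, nrow(x$homopolymer),
              if (nrow(x$homopolymer)) min(x$homopolymer$end - x$homopolymer$start + 1L) else "-"))
  invisible(x)
}

#' Locate maximal homopolymer runs
#'
#' @param sequence Character scalar nucleotide sequence.
#' @param min_run Minimum length for a run to be reported.
#' @return Data frame with columns `start`, `end` (1-based, closed) and
#'   `base`; runs are maximal and non-overlapping.
#' @export
find_homopolymer_runs <- function(sequence, min_run = 6L) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_run
  data.frame(start = starts[keep], end = ends[keep], base = r$values[keep],
             stringsAsFactors = FALSE)
}

# positions masked by a run: inside the run or within `pad` of its borders
homopolymer_mask <- function(runs, genome_length, pad = 1L) {
  mask <- logical(genome_length)
  if (nrow(runs)) {
    for (i in seq_len(nrow(runs))) {
      lo <- max(1L, runs$start[i] - pad)
      hi <- min(genome_length, runs$end[i] + pad)
      mask[lo:hi] <- TRUE
    }
  }
  mask
}

# strictly inside a run (no border padding)
homopolymer_inside <- function(runs, genome_length) {
  homopolymer_mask(runs, genome_length, pad = 0L)
}

#' Read a reference genome from FASTA
#'
#' @param path Path to a FASTA file; the first record is used.
#' @param homopolymer_min_run Passed to [plastome()].
#' @return A [plastome()] object.
#' @export
read_genome <- function(path, homopolymer_min_run = 6L) {
  ss <- readDNAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  nm <- sub("\\s.*$", "", names(ss)[1L])
  plastome(as.character(ss[[1L]]), name = nm,
           homopolymer_min_run = homopolymer_min_run)
}

#' Write a reference genome to FASTA
#'
#' @param genome A [plastome()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  ss <- DNAStringSet(genome$sequence)
  names(ss) <- genome$name
  writeXStringSet(ss, path)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' @param x Character vector of A/C/G/T sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) as.character(reverseComplement(DNAString(s))),
         character(1L), USE.NAMES = FALSE)
}

complement_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[b])
}

genome_chars <- function(genome) {
  strsplit(genome$sequence, "", fixed = TRUE)[[1L]]
}
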