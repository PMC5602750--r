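#' Alignment filter parameters
#'
#' Quality control applied before pileup: a read is retained only when a
#' large enough fraction of it is aligned and the aligned part is similar
#' enough to the reference. Defaults (0.98/0.98) correspond to stringent
#' read-mapping quality control used for low-frequency variant detection.
#'
#' @param min_length_fraction Minimum (aligned length / read length).
#' @param min_similarity Minimum (matching bases / aligned length).
#' @return List of class `alignment_filter_params`.
#' @export
alignment_filter_params <- function(min_length_fraction = 0.98,
                                    min_similarity = 0.98) {
  if (min_length_fraction <= 0 || min_length_fraction > 1 ||
      min_similarity <= 0 || min_similarity > 1)
    stop("filter fractions must lie in (0, 1]")
  structure(list(min_length_fraction = min_length_fraction,
                 min_similarity = min_similarity),
            class = "alignment_filter_params")
}

cigar_op_sums <- function(cigar) {
  n <- length(cigar)
  out <- matrix(0L, nrow = n, ncol = 5L,
                dimnames = list(NULL, c("M", "I", "D", "S", "N")))
  simple <- grepl("^\\d+M$", cigar)
  out[simple, "M"] <- as.integer(sub("M$", "", cigar[simple]))
  idx <- which(!simple & cigar != "*" & !is.na(cigar))
  if (length(idx)) {
    toks <- regmatches(cigar[idx], gregexpr("\\d+[MIDNSHP=X]", cigar[idx]))
    for (k in seq_along(idx)) {
      tk <- toks[[k]]
      len <- as.integer(sub("[MIDNSHP=X]$", "", tk))
      op <- sub("^\\d+", "", tk)
      op[op %in% c("=", "X")] <- "M"
      for (o in c("M", "I", "D", "S", "N"))
        out[idx[k], o] <- sum(len[op == o])
    }
  }
  out
}

#' Read alignments from a SAM/BAM file
#'
#' Converts SAM to BAM via Rsamtools and extracts the fields the pipeline
#' needs, computing per-read aligned length and matching-base count from
#' the CIGAR string and the `NM` tag (or, for ungapped reads, by direct
#' comparison with the reference when `NM` is absent). Unmapped records are
#' dropped with a message.
#'
#' @param path Path to a SAM or BAM file.
#' @param genome Optional [plastome()]; used to compute match counts when
#'   the `NM` tag is missing.
#' @return Data frame with columns `qname`, `flag`, `strand`, `pos`,
#'   `mapq`, `cigar`, `seq` (reference-plus-strand orientation, as stored
#'   in SAM), `read_length`, `aligned_length`, `nmatch`.
#' @export
read_alignments <- function(path, genome = NULL) {
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path
         else Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                               indexDestination = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "mapq", "cigar", "seq", "qwidth"),
    tag = "NM")
  x <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(x$qname)
  if (n == 0L) return(empty_alignments())
  unmapped <- bitwAnd(x$flag, 4L) > 0L | is.na(x$pos) | x$cigar %in% c(NA, "*")
  if (any(unmapped))
    message(sprintf("read_alignments: dropped %d unmapped/malformed record(s)",
                    sum(unmapped)))
  keep <- which(!unmapped)
  ops <- cigar_op_sums(x$cigar[keep])
  aligned <- ops[, "M"] + ops[, "I"]
  nm <- x$tag$NM[keep]
  seqs <- as.character(x$seq[keep])
  if (is.null(nm) || all(is.na(nm))) {
    if (is.null(genome))
      stop("alignments lack NM tags; supply `genome` to compute matches")
    if (any(ops[, c("I", "D", "N", "S")] > 0L))
      stop("cannot recover match counts for gapped reads without NM tags")
    ref <- substring(genome$sequence, x$pos[keep], x$pos[keep] + ops[, "M"] - 1L)
    mism <- mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)), seqs, ref,
                   USE.NAMES = FALSE)
    nm <- as.integer(mism)
  } else {
    nm[is.na(nm)] <- 0L
  }
  mismatches <- pmax(0L, nm - ops[, "I"] - ops[, "D"])
  data.frame(
    qname = x$qname[keep],
    flag = x$flag[keep],
    strand = ifelse(bitwAnd(x$flag[keep], 16L) > 0L, "-", "+"),
    pos = x$pos[keep],
    mapq = x$mapq[keep],
    cigar = x$cigar[keep],
    seq = seqs,
    read_length = x$qwidth[keep],
    aligned_length = aligned,
    nmatch = ops[, "M"] - mismatches,
    stringsAsFactors = FALSE
  )
}

empty_alignments <- function() {
  data.frame(qname = character(), flag = integer(), strand = character(),
             pos = integer(), mapq = integer(), cigar = character(),
             seq = character(), read_length = integer(),
             aligned_length = integer(), nmatch = integer(),
             stringsAsFactors = FALSE)
}

#' Filter alignments by length fraction and similarity
#'
#' Retains exactly the mapped reads with
#' `aligned_length / read_length >= min_length_fraction` and
#' `nmatch / aligned_length >= min_similarity`, preserving input order.
#' Unmapped or malformed records are skipped with a message.
#'
#' @param aln Alignment data frame from [read_alignments()] or
#'   [simulate_reads()].
#' @param params An [alignment_filter_params()].
#' @return The retained subset, with attributes `n_skipped` (malformed) and
#'   `n_filtered` (failing the thresholds).
#' @export
filter_alignments <- function(aln, params = alignment_filter_params()) {
  malformed <- is.na(aln$pos) | is.na(aln$cigar) | aln$cigar == "*" |
    bitwAnd(aln$flag, 4L) > 0L | aln$aligned_length <= 0L
  if (any(malformed))
    message(sprintf("filter_alignments: skipped %d unmapped/malformed record(s)",
                    sum(malformed)))
  a <- aln[!malformed, , drop = FALSE]
  keep <- (a$aligned_length / a$read_length) >= params$min_length_fraction &
    (a$nmatch / a$aligned_length) >= params$min_similarity
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(malformed)
  attr(out, "n_filtered") <- sum(!keep)
  out
}

# (ref position, read base index) pairs for one gapped read
walk_cigar <- function(cigar, pos, seq_ints) {
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  len <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  op <- sub("^\\d+", "", toks)
  refpos <- integer(0)
  base <- integer(0)
  rp <- pos
  qp <- 1L
  for (k in seq_along(op)) {
    o <- op[k]; l <- len[k]
    if (o %in% c("M", "=", "X")) {
      refpos <- c(refpos, rp:(rp + l - 1L))
      base <- c(base, seq_ints[qp:(qp + l - 1L)])
      rp <- rp + l; qp <- qp + l
    } else if (o %in% c("I", "S")) {
      qp <- qp + l
    } else if (o %in% c("D", "N")) {
      rp <- rp + l
    }  # H, P: no-op
  }
  list(refpos = refpos, base = base)
}

#' Build a per-position base-count pileup
#'
#' Reduces filtered alignments to one row per covered reference position
#' with counts of each read base. SAM stores read sequences in reference
#' plus-strand orientation, so counts are plus-strand counts regardless of
#' the aligned strand; transcript-strand interpretation is applied later by
#' the edit caller. Reads with indels contribute only their aligned
#' match/mismatch positions; non-ACGT read bases are ignored.
#'
#' @param aln Alignment data frame.
#' @param genome A [plastome()].
#' @return Data frame with columns `position`, `ref_base`, `depth`,
#'   `count_A`, `count_C`, `count_G`, `count_T`, sorted by position.
#' @export
build_pileup <- function(aln, genome) {
  L <- genome$length
  if (nrow(aln) == 0L) return(empty_pileup())
  ops <- cigar_op_sums(aln$cigar)
  ref_span <- ops[, "M"] + ops[, "D"] + ops[, "N"]
  if (any(aln$pos < 1L) || any(aln$pos + ref_span - 1L > L))
    stop("data error: alignment coordinates outside the genome")
  base_code <- utf8ToInt(paste0(DNA_BASES, collapse = ""))
  simple <- grepl("^\\d+M$", aln$cigar)
  refpos <- integer(0)
  baseidx <- integer(0)
  if (any(simple)) {
    w <- nchar(aln$seq[simple])
    refpos <- sequence(w) + rep(aln$pos[simple] - 1L, w)
    baseidx <- match(utf8ToInt(paste(aln$seq[simple], collapse = "")), base_code)
  }
  if (any(!simple)) {
    for (i in which(!simple)) {
      ints <- match(utf8ToInt(aln$seq[i]), base_code)
      wk <- walk_cigar(aln$cigar[i], aln$pos[i], ints)
      refpos <- c(refpos, wk$refpos)
      baseidx <- c(baseidx, wk$base)
    }
  }
  ok <- !is.na(baseidx)
  counts <- tabulate((refpos[ok] - 1L) * 4L + baseidx[ok], nbins = 4L * L)
  cm <- matrix(counts, nrow = 4L)
  depth <- colSums(cm)
  covered <- which(depth > 0L)
  chars <- genome_chars(genome)
  data.frame(
    position = covered,
    ref_base = chars[covered],
    depth = as.integer(depth[covered]),
    count_A = as.integer(cm[1L, covered]),
    count_C = as.integer(cm[2L, covered]),
    count_G = as.integer(cm[3L, covered]),
    count_T = as.integer(cm[4L, covered]),
    stringsAsFactors = FALSE
  )
}

empty_pileup <- function() {
  data.frame(position = integer(), ref_base = character(), depth = integer(),
             count_A = integer(), count_C = integer(), count_G = integer(),
             count_T = integer(), stringsAsFactors = FALSE)
}

#' Write a pileup as TSV
#' @param pileup Pileup data frame from [build_pileup()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileup, path) {
  write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
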