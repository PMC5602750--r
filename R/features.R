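#' Construct a feature table
#'
#' Genomic features are held as a plain data frame with one row per interval
#' (so a two-exon CDS contributes two `CDS` rows sharing a `feature_id`,
#' plus one `intron` row). Intervals are 1-based and closed; `exon_rank`
#' orders exons in transcript (5' to 3') direction, so for a minus-strand
#' gene rank 1 is the rightmost interval.
#'
#' @param feature_id Gene identifier (shared across a gene's intervals).
#' @param feature_class One of `"CDS"`, `"tRNA"`, `"rRNA"`, `"intron"`.
#' @param start,end 1-based closed interval bounds.
#' @param strand `"+"` or `"-"`.
#' @param phase CDS phase (0/1/2); `NA` for non-CDS rows.
#' @param exon_rank Transcript-order rank of the interval within its gene.
#' @return Data frame of class `feature_table`.
#' @export
feature_table <- function(feature_id = character(), feature_class = character(),
                          start = integer(), end = integer(),
                          strand = character(), phase = NA_integer_,
                          exon_rank = 1L) {
  n <- length(feature_id)
  df <- data.frame(
    feature_id = as.character(feature_id),
    feature_class = as.character(feature_class),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    phase = rep_len(as.integer(phase), n),
    exon_rank = rep_len(as.integer(exon_rank), n),
    stringsAsFactors = FALSE
  )
  validate_features(df)
  class(df) <- c("feature_table", "data.frame")
  df
}

validate_features <- function(df) {
  if (!nrow(df)) return(invisible(df))
  bad <- !df$feature_class %in% c("CDS", "tRNA", "rRNA", "intron")
  if (any(bad)) stop("unknown feature_class: ",
                     paste(unique(df$feature_class[bad]), collapse = ", "))
  if (any(df$end < df$start)) stop("feature end < start")
  if (any(!df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  invisible(df)
}

#' Write features to GFF3
#'
#' @param features A [feature_table()].
#' @param path Output path.
#' @param genome Optional [plastome()] providing the seqname and length.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, genome = NULL) {
  seqname <- if (!is.null(genome)) genome$name else "plastome"
  if (nrow(features) == 0L) {
    lines <- "##gff-version 3"
    if (!is.null(genome))
      lines <- c(lines, sprintf("##sequence-region %s 1 %d", seqname, genome$length))
    writeLines(lines, path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = features$strand
  )
  S4Vectors::mcols(gr)$type <- features$feature_class
  S4Vectors::mcols(gr)$phase <- features$phase
  S4Vectors::mcols(gr)$ID <- paste0(features$feature_id, ".",
                                    features$feature_class, ".",
                                    features$exon_rank)
  S4Vectors::mcols(gr)$gene_id <- features$feature_id
  S4Vectors::mcols(gr)$exon_rank <- features$exon_rank
  if (!is.null(genome))
    GenomeInfoDb::seqlengths(gr) <- stats::setNames(genome$length, seqname)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read features from GFF3
#'
#' Recognises `CDS`, `tRNA`, `rRNA` and `intron` records; other types are
#' ignored. The gene identifier is taken from the `gene_id` attribute when
#' present, otherwise from `ID`/`Parent`.
#'
#' @param path Path to a GFF3 file.
#' @return A [feature_table()].
#' @export
read_features <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  keep <- as.character(gr$type) %in% c("CDS", "tRNA", "rRNA", "intron")
  gr <- gr[keep]
  if (length(gr) == 0L) return(feature_table())
  mc <- S4Vectors::mcols(gr)
  gene_id <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id) else NULL
  if (is.null(gene_id) || all(is.na(gene_id))) {
    gene_id <- if ("ID" %in% names(mc)) as.character(mc$ID) else
      paste0("feature", seq_along(gr))
    gene_id <- sub("\\.(CDS|tRNA|rRNA|intron)\\..*$", "", gene_id)
  }
  phase <- if ("phase" %in% names(mc)) suppressWarnings(as.integer(mc$phase)) else NA_integer_
  rank <- if ("exon_rank" %in% names(mc)) suppressWarnings(as.integer(mc$exon_rank)) else NA_integer_
  df <- feature_table(
    feature_id = gene_id,
    feature_class = as.character(mc$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    phase = phase,
    exon_rank = ifelse(is.na(rank), 1L, rank)
  )
  # recover transcript-order ranks when absent
  for (g in unique(df$feature_id)) {
    sel <- which(df$feature_id == g & df$feature_class == "CDS")
    if (length(sel) > 1L && anyDuplicated(df$exon_rank[sel])) {
      ord <- order(df$start[sel], decreasing = df$strand[sel][1L] == "-")
      df$exon_rank[sel][ord] <- seq_along(sel)
    }
  }
  df
}

# Per-position feature annotation of the genome: class ("CDS","tRNA","rRNA",
# "intron" or "IGS"), strand (NA for IGS) and gene id. Errors on overlapping
# features from different genes.
position_annotation <- function(features, genome_length) {
  cls <- rep("IGS", genome_length)
  strand <- rep(NA_character_, genome_length)
  gene <- rep(NA_character_, genome_length)
  if (nrow(features)) {
    for (i in seq_len(nrow(features))) {
      idx <- features$start[i]:features$end[i]
      clash <- !is.na(gene[idx]) & gene[idx] != features$feature_id[i]
      if (any(clash)) {
        stop(sprintf("annotation error: feature '%s' overlaps '%s' at position %d",
                     features$feature_id[i],
                     gene[idx][clash][1L], idx[clash][1L]))
      }
      cls[idx] <- features$feature_class[i]
      strand[idx] <- features$strand[i]
      gene[idx] <- features$feature_id[i]
    }
  }
  list(class = cls, strand = strand, gene = gene)
}

# Exon rows of one gene's CDS, in transcript order.
cds_exons <- function(features, gene) {
  ex <- features[features$feature_id == gene & features$feature_class == "CDS", ,
                 drop = FALSE]
  if (!nrow(ex)) stop("no CDS rows for gene ", gene)
  ex[order(ex$exon_rank), , drop = FALSE]
}

# Spliced CDS sequence of a gene, in transcript orientation.
spliced_cds <- function(features, genome, gene) {
  ex <- cds_exons(features, gene)
  parts <- substring(genome$sequence, ex$start, ex$end)
  if (ex$strand[1L] == "-") parts <- revcomp(parts)
  paste(parts, collapse = "")
}

# 1-based offset of a genomic position within the spliced CDS of `gene`,
# walking exons in transcript orientation. NA if outside all exons.
cds_offset <- function(features, gene, position) {
  ex <- cds_exons(features, gene)
  off <- 0L
  for (i in seq_len(nrow(ex))) {
    w <- ex$end[i] - ex$start[i] + 1L
    if (position >= ex$start[i] && position <= ex$end[i]) {
      within <- if (ex$strand[i] == "+") position - ex$start[i] + 1L
                else ex$end[i] - position + 1L
      return(off + within)
    }
    off <- off + w
  }
  NA_integer_
}
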