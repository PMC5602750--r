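# Small shared fixtures for unit tests.

small_config <- function(...) {
  sim_config(genome_length = 3000L, n_genes = 4L, intron_genes = 1L,
             trna_genes = 1L, read_length = 60L, mean_coverage = 40,
             error_rate = 0, n_edits = 8L, seed = 42L, ...)
}

# alignment data frame matching the read_alignments() column contract
make_aln <- function(pos, seq, flag = 0L, read_length = nchar(seq),
                     aligned_length = nchar(seq), nmatch = nchar(seq),
                     cigar = sprintf("%dM", nchar(seq))) {
  n <- length(pos)
  if (n == 0L) return(plastedit:::empty_alignments())
  data.frame(
    qname = sprintf("r%03d", seq_len(n)),
    flag = rep_len(as.integer(flag), n),
    strand = ifelse(bitwAnd(rep_len(as.integer(flag), n), 16L) > 0L, "-", "+"),
    pos = as.integer(pos),
    mapq = 60L,
    cigar = rep_len(cigar, n),
    seq = seq,
    read_length = rep_len(as.integer(read_length), n),
    aligned_length = rep_len(as.integer(aligned_length), n),
    nmatch = rep_len(as.integer(nmatch), n),
    stringsAsFactors = FALSE
  )
}

# truth table row(s) built by hand
make_truth <- function(position, strand, edit_type, eff, tissues = "leaf",
                       feature_class = "IGS") {
  out <- data.frame(position = as.integer(position), strand = strand,
                    edit_type = edit_type, feature_class = feature_class,
                    feature_id = "", in_homopolymer = FALSE,
                    stringsAsFactors = FALSE)
  eff <- as.data.frame(eff)
  names(eff) <- paste0("eff_", tissues)
  cbind(out, eff)
}

# pileup row(s) built by hand
make_pileup <- function(position, ref_base, count_A = 0L, count_C = 0L,
                        count_G = 0L, count_T = 0L) {
  if (length(position) == 0L) return(plastedit:::empty_pileup())
  data.frame(position = as.integer(position), ref_base = ref_base,
             depth = as.integer(count_A + count_C + count_G + count_T),
             count_A = as.integer(count_A), count_C = as.integer(count_C),
             count_G = as.integer(count_G), count_T = as.integer(count_T),
             stringsAsFactors = FALSE)
}

# single-gene toy genome: a CDS (given as codon vector) embedded in a
# neutral background, on either strand, optionally split by an intron
toy_gene <- function(codons, strand = "+", flank = 30L, intron_after = NA,
                     intron_seq = NULL, gene = "geneX") {
  cds <- paste(codons, collapse = "")
  if (!is.na(intron_after)) {
    if (is.null(intron_seq))
      intron_seq <- paste0("GT", strrep("A", 20), "AG")
    ex1 <- substr(cds, 1L, intron_after)
    ex2 <- substr(cds, intron_after + 1L, nchar(cds))
    genomic <- paste0(ex1, intron_seq, ex2)
  } else {
    genomic <- cds
  }
  if (strand == "-") genomic <- revcomp(genomic)
  bg <- strrep("A", flank)  # neutral flank, no C/T confusion on '+'
  seqn <- paste0(bg, genomic, bg)
  genome <- plastome(seqn, name = "toy")
  gstart <- flank + 1L
  gend <- flank + nchar(genomic)
  if (is.na(intron_after)) {
    feats <- feature_table(gene, "CDS", gstart, gend, strand, 0L, 1L)
  } else {
    l1 <- intron_after; il <- nchar(intron_seq); l2 <- nchar(cds) - intron_after
    phase2 <- (3L - l1 %% 3L) %% 3L
    if (strand == "+") {
      feats <- rbind(
        feature_table(gene, "CDS", gstart, gstart + l1 - 1L, "+", 0L, 1L),
        feature_table(gene, "intron", gstart + l1, gstart + l1 + il - 1L, "+", NA, 1L),
        feature_table(gene, "CDS", gstart + l1 + il, gend, "+", phase2, 2L))
    } else {
      feats <- rbind(
        feature_table(gene, "CDS", gend - l1 + 1L, gend, "-", 0L, 1L),
        feature_table(gene, "intron", gstart + l2, gstart + l2 + il - 1L, "-", NA, 1L),
        feature_table(gene, "CDS", gstart, gstart + l2 - 1L, "-", phase2, 2L))
    }
    class(feats) <- c("feature_table", "data.frame")
  }
  list(genome = genome, features = feats, gstart = gstart, gend = gend)
}

# a CDS of n codons with a chosen codon placed at a given codon index;
# filler codons are GGT (Gly), start ATG unless overridden, stop TAA
toy_cds_with <- function(codon, index, n_codons = max(index + 1L, 20L),
                         start_codon = "ATG", strand = "+") {
  codons <- c(start_codon, rep("GGT", n_codons - 2L), "TAA")
  codons[index] <- codon
  toy_gene(codons, strand = strand)
}
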