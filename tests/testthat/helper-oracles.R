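# Independent brute-force re-implementations used as oracles on small
# inputs. These deliberately share no code with the package internals.

naive_pileup <- function(aln, genome) {
  L <- genome$length
  counts <- matrix(0L, nrow = 4L, ncol = L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_len(nrow(aln))) {
    stopifnot(grepl("^\\d+M$", aln$cigar[i]))
    bases <- strsplit(aln$seq[i], "", fixed = TRUE)[[1L]]
    for (j in seq_along(bases)) {
      p <- aln$pos[i] + j - 1L
      b <- bases[j]
      if (b %in% rownames(counts)) counts[b, p] <- counts[b, p] + 1L
    }
  }
  covered <- which(colSums(counts) > 0L)
  ref <- strsplit(genome$sequence, "", fixed = TRUE)[[1L]]
  data.frame(position = covered, ref_base = ref[covered],
             depth = as.integer(colSums(counts)[covered]),
             count_A = counts["A", covered], count_C = counts["C", covered],
             count_G = counts["G", covered], count_T = counts["T", covered],
             stringsAsFactors = FALSE)
}

# exhaustive per-position recount of the calling rules
naive_call <- function(pileup, genome, features, params) {
  conv <- list(C = c(alt = "T", orient = "+", type = "C_to_U"),
               T = c(alt = "C", orient = "+", type = "U_to_C"),
               G = c(alt = "A", orient = "-", type = "C_to_U"),
               A = c(alt = "G", orient = "-", type = "U_to_C"))
  # per-position feature strand
  strand_of <- function(p) {
    if (nrow(features) == 0L) return(NA_character_)
    hit <- features$start <= p & features$end >= p
    if (!any(hit)) return(NA_character_)
    features$strand[which(hit)[1L]]
  }
  # homopolymer mask (run >= min, padded by 1)
  ref <- strsplit(genome$sequence, "", fixed = TRUE)[[1L]]
  masked <- logical(genome$length)
  run_start <- 1L
  for (p in 2L:(genome$length + 1L)) {
    if (p > genome$length || ref[p] != ref[run_start]) {
      if (p - run_start >= params$homopolymer_min_run) {
        lo <- max(1L, run_start - 1L); hi <- min(genome$length, p)
        masked[lo:min(hi, genome$length)] <- TRUE
      }
      run_start <- p
    }
  }
  rows <- list()
  for (i in seq_len(nrow(pileup))) {
    rb <- pileup$ref_base[i]
    cv <- conv[[rb]]
    fs <- strand_of(pileup$position[i])
    if (!is.na(fs) && fs != cv[["orient"]]) next
    alt_n <- pileup[[paste0("count_", cv[["alt"]])]][i]
    d <- pileup$depth[i]
    if (d >= params$min_coverage && alt_n >= params$min_count &&
        alt_n / d >= params$min_frequency) {
      rows[[length(rows) + 1L]] <- data.frame(
        position = pileup$position[i],
        transcript_strand = if (is.na(fs)) "unassigned" else fs,
        orientation = cv[["orient"]], edit_type = cv[["type"]],
        edited_count = alt_n, depth = d, efficiency = alt_n / d,
        homopolymer_flag = masked[pileup$position[i]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# mirror a dataset: reverse-complement genome, features and alignments
mirror_dataset <- function(genome, features, aln) {
  L <- genome$length
  g2 <- plastome(revcomp(genome$sequence), name = genome$name)
  f2 <- features
  if (nrow(f2)) {
    s <- L - f2$end + 1L
    e <- L - f2$start + 1L
    f2$start <- s; f2$end <- e
    f2$strand <- ifelse(f2$strand == "+", "-", "+")
  }
  a2 <- aln
  w <- nchar(aln$seq)
  a2$pos <- L - (aln$pos + w - 1L) + 1L
  a2$seq <- revcomp(aln$seq)
  a2$flag <- bitwXor(aln$flag, 16L)
  a2$strand <- ifelse(a2$flag == 16L, "-", "+")
  list(genome = g2, features = f2, aln = a2)
}
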