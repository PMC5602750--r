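#' Configuration for the synthetic plastome simulator
#'
#' Bundles every tunable of the synthetic-data generator. The defaults
#' describe the desk-scale validation scenario the package is tested under:
#' a 20 kb miniature plastome carrying a dozen genes on both strands, 100
#' planted conversions with per-tissue efficiencies spanning 10--95%,
#' coverage in the hundreds and a low uniform substitution error rate.
#'
#' @param genome_length Genome size in bp.
#' @param n_genes Total number of genes (coding plus tRNA).
#' @param intron_genes Number of CDS genes carrying a single intron.
#' @param trna_genes Number of tRNA genes (counted within `n_genes`).
#' @param read_length Read length in bp.
#' @param mean_coverage Expected fold coverage.
#' @param error_rate Per-base probability of a uniform substitution error.
#' @param n_edits Number of planted editing sites.
#' @param efficiency_range Length-2 numeric; true efficiencies are drawn
#'   uniformly from this range, independently per tissue.
#' @param tissue_labels Character vector of tissue names (order matters:
#'   differential direction is reported as first minus second).
#' @param seed Integer seed; fully determines all simulator output.
#' @param gc_content Background GC fraction (plastome-like default 0.37).
#' @param u_to_c_fraction Fraction of planted edits that are U-to-C rather
#'   than C-to-U (plastid editing is overwhelmingly C-to-U).
#' @param acg_start_genes Number of CDS genes whose annotated initiation
#'   codon is ACG instead of ATG (start-codon-creation test genes).
#' @param homopolymer_truth_sites Number of planted edits deliberately placed
#'   inside a homopolymer run (expected to be masked by the caller).
#' @param tissue_specific_sites Number of planted edits forced to efficiency
#'   0 in the second tissue (tissue-specific).
#' @param forced_differential_sites Number of planted edits forced to differ
#'   by more than 20 percentage points between the first two tissues.
#' @param expression_multiplier Optional named numeric vector of per-gene
#'   expression multipliers for read placement; default uniform placement.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 20000L, n_genes = 12L,
                       intron_genes = 2L, trna_genes = 2L,
                       read_length = 100L, mean_coverage = 200,
                       error_rate = 0.002, n_edits = 100L,
                       efficiency_range = c(0.10, 0.95),
                       tissue_labels = c("leaf", "flower"),
                       seed = 1L, gc_content = 0.37,
                       u_to_c_fraction = 0.08,
                       acg_start_genes = 1L,
                       homopolymer_truth_sites = 1L,
                       tissue_specific_sites = 1L,
                       forced_differential_sites = 1L,
                       expression_multiplier = NULL) {
  cfg <- list(
    genome_length = as.integer(genome_length), n_genes = as.integer(n_genes),
    intron_genes = as.integer(intron_genes), trna_genes = as.integer(trna_genes),
    read_length = as.integer(read_length), mean_coverage = mean_coverage,
    error_rate = error_rate, n_edits = as.integer(n_edits),
    efficiency_range = as.numeric(efficiency_range),
    tissue_labels = as.character(tissue_labels), seed = as.integer(seed),
    gc_content = gc_content, u_to_c_fraction = u_to_c_fraction,
    acg_start_genes = as.integer(acg_start_genes),
    homopolymer_truth_sites = as.integer(homopolymer_truth_sites),
    tissue_specific_sites = as.integer(tissue_specific_sites),
    forced_differential_sites = as.integer(forced_differential_sites),
    expression_multiplier = expression_multiplier
  )
  if (cfg$genome_length <= 0L) stop("configuration error: genome_length must be positive")
  if (cfg$error_rate < 0 || cfg$error_rate >= 1)
    stop("configuration error: error_rate must be in [0, 1)")
  if (length(cfg$efficiency_range) != 2L ||
      any(cfg$efficiency_range < 0) || any(cfg$efficiency_range > 1) ||
      diff(cfg$efficiency_range) < 0)
    stop("configuration error: efficiency_range must be an ascending pair in [0, 1]")
  if (cfg$trna_genes + max(0L, cfg$intron_genes) > cfg$n_genes && cfg$n_genes > 0L)
    stop("configuration error: intron_genes + trna_genes exceed n_genes")
  if (cfg$trna_genes > cfg$n_genes)
    stop("configuration error: trna_genes exceed n_genes")
  if (!length(cfg$tissue_labels)) stop("configuration error: no tissue_labels")
  if (cfg$read_length <= 0L) stop("configuration error: read_length must be positive")
  class(cfg) <- "sim_config"
  cfg
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- DNA_BASES
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Generate a miniature plastome and its gene models
#'
#' Lays out non-overlapping stranded genes (plain CDS, intron-containing
#' CDS, and tRNA) separated by intergenic spacers on a random background of
#' the configured GC content. Every CDS starts with ATG (or ACG for the
#' designated start-creation test genes), ends with a stop codon, contains
#' no internal stop codon, and has spliced length divisible by 3. One CDS
#' gene carries a CCC-CCC codon pair so the genome is guaranteed to contain
#' a homopolymer run of length >= 6 inside a gene.
#'
#' @param config A [sim_config()].
#' @return List with elements `genome` (a [plastome()]) and `features`
#'   (a [feature_table()]).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  gc <- config$gc_content
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  chars <- sample(DNA_BASES, L, replace = TRUE, prob = p)

  feats <- feature_table()
  if (config$n_genes > 0L) {
    n_cds <- config$n_genes - config$trna_genes
    is_trna <- c(rep(FALSE, n_cds), rep(TRUE, config$trna_genes))
    has_intron <- c(seq_len(n_cds) <= config$intron_genes,
                    rep(FALSE, config$trna_genes))
    acg_start <- c(seq_len(n_cds) > n_cds - config$acg_start_genes,
                   rep(FALSE, config$trna_genes))
    # homopolymer host: first CDS gene that is neither intron- nor ACG-flagged
    hp_candidates <- which(!is_trna & !acg_start)
    hp_host <- if (length(hp_candidates)) hp_candidates[1L] else NA_integer_

    n <- config$n_genes
    n_codons <- ifelse(is_trna, NA_integer_, sample(100:220, n, replace = TRUE))
    intron_len <- ifelse(has_intron, sample(80:150, n, replace = TRUE), 0L)
    glen <- ifelse(is_trna, 72L, n_codons * 3L + intron_len)
    min_spacer <- 40L
    need <- sum(glen) + (n + 1L) * min_spacer
    if (need > L)
      stop(sprintf("configuration error: features (%d bp incl. spacers) exceed genome length (%d bp)",
                   need, L))
    extra <- L - need
    spacers <- min_spacer + as.vector(rmultinom(1L, extra, rep(1, n + 1L)))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    if (n >= 1L) strand[1L] <- "+"
    if (n >= 2L) strand[2L] <- "-"

    nonstop <- setdiff(all_codons(), STOP_CODONS)
    rows <- list()
    cursor <- 1L
    for (i in seq_len(n)) {
      cursor <- cursor + spacers[i]
      gstart <- cursor
      gend <- gstart + glen[i] - 1L
      if (is_trna[i]) {
        id <- sprintf("trn%s", LETTERS[sum(is_trna[seq_len(i)])])
        tseq <- paste(sample(DNA_BASES, 72L, replace = TRUE), collapse = "")
        ins <- if (strand[i] == "+") tseq else revcomp(tseq)
        chars[gstart:gend] <- strsplit(ins, "", fixed = TRUE)[[1L]]
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = id, feature_class = "tRNA", start = gstart, end = gend,
          strand = strand[i], phase = NA_integer_, exon_rank = 1L,
          stringsAsFactors = FALSE)
      } else {
        id <- sprintf("gene%02d", sum(!is_trna[seq_len(i)]))
        start_codon <- if (acg_start[i]) "ACG" else "ATG"
        body <- sample(nonstop, n_codons[i] - 2L, replace = TRUE)
        if (!is.na(hp_host) && i == hp_host && length(body) >= 4L) {
          j <- sample(2:(length(body) - 1L), 1L)
          body[j] <- "CCC"
          body[j + 1L] <- "CCC"
        }
        cds <- paste(c(start_codon, body, sample(STOP_CODONS, 1L)), collapse = "")
        if (has_intron[i]) {
          split_at <- 3L * sample(10:(n_codons[i] - 10L), 1L) + sample(0:2, 1L)
          ex1 <- substr(cds, 1L, split_at)
          ex2 <- substr(cds, split_at + 1L, nchar(cds))
          intr <- paste0("GT",
                         paste(sample(DNA_BASES, intron_len[i] - 4L, replace = TRUE),
                               collapse = ""), "AG")
          genomic <- paste0(ex1, intr, ex2)
          l1 <- nchar(ex1); il <- nchar(intr); l2 <- nchar(ex2)
          phase2 <- (3L - l1 %% 3L) %% 3L
          if (strand[i] == "+") {
            exon_iv <- data.frame(start = c(gstart, gstart + l1 + il),
                                  end = c(gstart + l1 - 1L, gend),
                                  phase = c(0L, phase2), exon_rank = c(1L, 2L))
            intron_iv <- c(gstart + l1, gstart + l1 + il - 1L)
          } else {
            genomic <- revcomp(genomic)
            # plus-coordinate layout: [rc(ex2)][rc(intron)][rc(ex1)]
            exon_iv <- data.frame(start = c(gend - l1 + 1L, gstart),
                                  end = c(gend, gstart + l2 - 1L),
                                  phase = c(0L, phase2), exon_rank = c(1L, 2L))
            intron_iv <- c(gstart + l2, gstart + l2 + il - 1L)
          }
          chars[gstart:gend] <- strsplit(genomic, "", fixed = TRUE)[[1L]]
          rows[[length(rows) + 1L]] <- data.frame(
            feature_id = id, feature_class = "CDS",
            start = exon_iv$start, end = exon_iv$end, strand = strand[i],
            phase = exon_iv$phase, exon_rank = exon_iv$exon_rank,
            stringsAsFactors = FALSE)
          rows[[length(rows) + 1L]] <- data.frame(
            feature_id = id, feature_class = "intron",
            start = intron_iv[1L], end = intron_iv[2L], strand = strand[i],
            phase = NA_integer_, exon_rank = 1L, stringsAsFactors = FALSE)
        } else {
          genomic <- if (strand[i] == "+") cds else revcomp(cds)
          chars[gstart:gend] <- strsplit(genomic, "", fixed = TRUE)[[1L]]
          rows[[length(rows) + 1L]] <- data.frame(
            feature_id = id, feature_class = "CDS", start = gstart, end = gend,
            strand = strand[i], phase = 0L, exon_rank = 1L,
            stringsAsFactors = FALSE)
        }
      }
      cursor <- gend + 1L
    }
    feats <- do.call(rbind, rows)
    class(feats) <- c("feature_table", "data.frame")
  }

  genome <- plastome(paste(chars, collapse = ""), name = "synthetic_plastome")
  list(genome = genome, features = feats)
}

# plus-strand (reference) substitution implied by an edit of a given
# transcript strand and type
edit_plus_bases <- function(strand, edit_type) {
  key <- paste(strand, edit_type)
  from <- c("+ C_to_U" = "C", "+ U_to_C" = "T",
            "- C_to_U" = "G", "- U_to_C" = "A")[key]
  to <- c("+ C_to_U" = "T", "+ U_to_C" = "C",
          "- C_to_U" = "A", "- U_to_C" = "G")[key]
  list(from = unname(from), to = unname(to))
}

#' Plant editing sites with per-tissue true efficiencies
#'
#' Selects eligible positions (transcript-strand C for C-to-U, T for U-to-C;
#' for intergenic positions either plus-strand orientation is allowed) and
#' draws per-tissue efficiencies uniformly from `config$efficiency_range`.
#' The truth table is guaranteed, when the configuration asks for it, to
#' contain edits in every available feature class and on both strands, a
#' tissue-specific edit (efficiency 0 in the second tissue), a pair of
#' tissues differing by more than 20 percentage points, and an edit inside
#' a homopolymer run (the caller is expected to mask it). All other edits
#' avoid homopolymer runs and their 1 bp borders.
#'
#' @param genome A [plastome()].
#' @param features A [feature_table()].
#' @param config A [sim_config()].
#' @return Data frame of class `truth_table` with columns `position`,
#'   `strand`, `edit_type`, `feature_class`, `feature_id`,
#'   `in_homopolymer`, and one `eff_<tissue>` column per tissue.
#' @export
plant_edits <- function(genome, features, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  L <- genome$length
  ann <- position_annotation(features, L)
  chars <- genome_chars(genome)
  mask <- homopolymer_mask(genome$homopolymer, L, pad = 1L)
  inside <- homopolymer_inside(genome$homopolymer, L)

  # orientation implied by the plus-strand base, per edit type
  orient_for <- function(type) {
    from_plus <- if (type == "C_to_U") "C" else "T"
    from_minus <- if (type == "C_to_U") "G" else "A"
    orient <- rep(NA_character_, L)
    plus_ok <- chars == from_plus & (is.na(ann$strand) | ann$strand == "+")
    minus_ok <- chars == from_minus & (is.na(ann$strand) | ann$strand == "-")
    orient[plus_ok] <- "+"
    orient[minus_ok] <- "-"
    orient
  }
  o_cu <- orient_for("C_to_U")
  o_uc <- orient_for("U_to_C")

  edge <- c(1L, L)
  eligible <- function(orient, use_mask = TRUE) {
    ok <- !is.na(orient) & !(seq_len(L) %in% edge)
    if (use_mask) ok <- ok & !mask
    which(ok)
  }

  n <- config$n_edits
  if (n == 0L) {
    out <- empty_truth(config)
    return(out)
  }
  n_uc <- min(n, round(config$u_to_c_fraction * n))
  n_cu <- n - n_uc
  n_hp <- min(config$homopolymer_truth_sites, n)

  pool_cu <- eligible(o_cu)
  pool_uc <- eligible(o_uc)
  pool_hp <- which(inside & !is.na(o_cu) & !(seq_len(L) %in% edge))

  chosen <- integer(0)
  ch_type <- character(0)
  take <- function(pos, type) {
    chosen <<- c(chosen, pos)
    ch_type <<- c(ch_type, type)
  }

  # guarantee class and strand coverage with C_to_U picks
  classes_avail <- intersect(c("CDS", "tRNA", "intron", "IGS"), unique(ann$class))
  for (cl in classes_avail) {
    cand <- setdiff(pool_cu[ann$class[pool_cu] == cl], chosen)
    if (length(cand) && length(chosen) < n_cu) take(resample(cand, 1L), "C_to_U")
  }
  for (st in c("+", "-")) {
    cand <- setdiff(pool_cu[o_cu[pool_cu] == st], chosen)
    covered <- any(o_cu[chosen[ch_type == "C_to_U"]] == st)
    if (!covered && length(cand) && length(chosen) < n_cu)
      take(resample(cand, 1L), "C_to_U")
  }
  # homopolymer-run sites
  n_hp_taken <- 0L
  if (n_hp > 0L) {
    cand <- setdiff(pool_hp, chosen)
    if (!length(cand))
      stop("configuration error: no eligible homopolymer-run position to plant")
    hp_pick <- resample(cand, min(n_hp, length(cand)))
    for (p in hp_pick) take(p, "C_to_U")
    n_hp_taken <- length(hp_pick)
  }
  # fill the rest (homopolymer picks count toward the C_to_U quota)
  n_cu_left <- max(0L, n - n_uc - sum(ch_type == "C_to_U"))
  cand <- setdiff(pool_cu, chosen)
  if (length(cand) < n_cu_left)
    stop("configuration error: not enough eligible positions for C_to_U edits")
  if (n_cu_left > 0L) for (p in resample(cand, n_cu_left)) take(p, "C_to_U")
  cand <- setdiff(pool_uc, chosen)
  if (length(cand) < n_uc)
    stop("configuration error: not enough eligible positions for U_to_C edits")
  if (n_uc > 0L) for (p in resample(cand, n_uc)) take(p, "U_to_C")

  orient <- ifelse(ch_type == "C_to_U", o_cu[chosen], o_uc[chosen])
  eff <- matrix(runif(length(chosen) * length(config$tissue_labels),
                      config$efficiency_range[1L], config$efficiency_range[2L]),
                nrow = length(chosen))
  colnames(eff) <- paste0("eff_", config$tissue_labels)

  in_hp <- inside[chosen]
  free <- which(!in_hp)
  nt <- length(config$tissue_labels)
  if (config$tissue_specific_sites > 0L && nt >= 2L && length(free)) {
    ts <- free[seq_len(min(config$tissue_specific_sites, length(free)))]
    eff[ts, 2L] <- 0
    free <- setdiff(free, ts)
  }
  if (config$forced_differential_sites > 0L && nt >= 2L && length(free)) {
    fd <- free[seq_len(min(config$forced_differential_sites, length(free)))]
    hi <- config$efficiency_range[2L]
    lo <- config$efficiency_range[1L]
    eff[fd, 1L] <- hi
    eff[fd, 2L] <- max(lo, hi - 0.30)
  }

  out <- data.frame(
    position = chosen, strand = orient, edit_type = ch_type,
    feature_class = ann$class[chosen],
    feature_id = ifelse(is.na(ann$gene[chosen]), "", ann$gene[chosen]),
    in_homopolymer = in_hp, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(eff))
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("truth_table", "data.frame")
  out
}

resample <- function(x, size) {
  # sample() misbehaves on length-1 numeric vectors
  if (length(x) == 1L) return(rep(x, length.out = size))
  sample(x, size)
}

empty_truth <- function(config) {
  out <- data.frame(position = integer(), strand = character(),
                    edit_type = character(), feature_class = character(),
                    feature_id = character(), in_homopolymer = logical(),
                    stringsAsFactors = FALSE)
  for (t in config$tissue_labels) out[[paste0("eff_", t)]] <- numeric()
  class(out) <- c("truth_table", "data.frame")
  out
}

#' Write a truth table as TSV
#'
#' @param truth A truth table from [plant_edits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth table TSV
#' @param path Path written by [write_truth()].
#' @return Truth table data frame.
#' @export
read_truth <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("truth_table", "data.frame")
  out
}

#' Simulate aligned reads for one tissue
#'
#' Draws ungapped single-end reads uniformly over the genome (optionally
#' weighted by per-gene expression multipliers) to the configured expected
#' depth. Each read overlapping a planted site carries the edited base with
#' probability equal to that tissue's true efficiency, independently per
#' read; every base is then substituted by a uniformly chosen different
#' base with probability `error_rate`. Alignments are correct by
#' construction and written as coordinate-sorted SAM with `@SQ` header and
#' `NM` tags.
#'
#' @param genome A [plastome()].
#' @param truth Truth table from [plant_edits()] (may have zero rows).
#' @param config A [sim_config()].
#' @param tissue One of `config$tissue_labels`.
#' @param path Optional output SAM path; when `NULL` no file is written.
#' @param features Optional [feature_table()], required when
#'   `config$expression_multiplier` is used.
#' @return Invisibly, an alignment data frame (see [read_alignments()] for
#'   the column contract).
#' @export
simulate_reads <- function(genome, truth, config, tissue, path = NULL,
                           features = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ti <- match(tissue, config$tissue_labels)
  if (is.na(ti)) stop("configuration error: unknown tissue '", tissue, "'")
  set.seed(config$seed + 7919L * ti)

  L <- genome$length
  rl <- config$read_length
  if (rl > L) stop("configuration error: read_length exceeds genome_length")
  n_reads <- as.integer(round(L * config$mean_coverage / rl))
  n_start <- L - rl + 1L

  if (!is.null(config$expression_multiplier)) {
    if (is.null(features))
      stop("features required when expression_multiplier is set")
    ann <- position_annotation(features, L)
    w <- rep(1, n_start)
    mid <- seq_len(n_start) + as.integer(rl / 2)
    g <- ann$gene[mid]
    known <- !is.na(g) & g %in% names(config$expression_multiplier)
    w[known] <- config$expression_multiplier[g[known]]
    starts <- sample.int(n_start, n_reads, replace = TRUE, prob = w)
  } else {
    starts <- sample.int(n_start, n_reads, replace = TRUE)
  }
  starts <- sort(starts)
  seqs <- substring(genome$sequence, starts, starts + rl - 1L)

  # plant edits read-by-read
  effcol <- paste0("eff_", tissue)
  if (nrow(truth)) {
    for (i in seq_len(nrow(truth))) {
      pos <- truth$position[i]
      sub <- edit_plus_bases(truth$strand[i], truth$edit_type[i])
      idx <- which(starts >= pos - rl + 1L & starts <= pos)
      if (!length(idx)) next
      hit <- idx[runif(length(idx)) < truth[[effcol]][i]]
      if (!length(hit)) next
      off <- pos - starts[hit] + 1L
      substring(seqs[hit], off, off) <- sub$to
    }
  }

  # uniform substitution errors on the flattened base vector
  base_code <- utf8ToInt(paste0(DNA_BASES, collapse = ""))
  ints <- match(utf8ToInt(paste(seqs, collapse = "")), base_code)
  if (config$error_rate > 0) {
    err <- which(runif(length(ints)) < config$error_rate)
    if (length(err)) {
      shift <- sample.int(3L, length(err), replace = TRUE)
      ints[err] <- ((ints[err] - 1L + shift) %% 4L) + 1L
    }
  }
  ref_ints <- match(utf8ToInt(paste(substring(genome$sequence, starts,
                                              starts + rl - 1L),
                                    collapse = "")), base_code)
  mismatch <- matrix(ints != ref_ints, nrow = rl)
  nm <- as.integer(colSums(mismatch))
  big <- intToUtf8(base_code[ints])
  seqs <- substring(big, seq(1L, by = rl, length.out = n_reads),
                    seq(rl, by = rl, length.out = n_reads))

  flag <- sample(c(0L, 16L), n_reads, replace = TRUE)
  aln <- data.frame(
    qname = sprintf("%s_read_%07d", tissue, seq_len(n_reads)),
    flag = flag,
    strand = ifelse(flag == 16L, "-", "+"),
    pos = starts,
    mapq = 60L,
    cigar = sprintf("%dM", rl),
    seq = seqs,
    read_length = rl,
    aligned_length = rl,
    nmatch = rl - nm,
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) write_sam(aln, genome, path)
  invisible(aln)
}

#' Write an alignment data frame as SAM
#'
#' @param aln Alignment data frame (see [read_alignments()]).
#' @param genome A [plastome()] providing the `@SQ` header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, genome, path) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", genome$name, genome$length))
  nm <- aln$aligned_length - aln$nmatch
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
                  aln$qname, aln$flag, genome$name, aln$pos, aln$mapq,
                  aln$cigar, aln$seq, strrep("I", nchar(aln$seq)), nm)
  con <- file(path, open = "wb")  # fixed newlines for byte-identical output
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Simulate a complete per-tissue dataset on disk
#'
#' Writes the genome FASTA, the feature GFF3, one SAM per tissue and the
#' truth TSV into `outdir`. All outputs are byte-identical across reruns
#' with the same configuration.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the simulated objects and file paths.
#' @export
simulate_dataset <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genome(config)
  truth <- plant_edits(gen$genome, gen$features, config)
  paths <- list(
    genome = file.path(outdir, "genome.fasta"),
    features = file.path(outdir, "features.gff3"),
    truth = file.path(outdir, "truth.tsv"),
    sam = stats::setNames(file.path(outdir, paste0(config$tissue_labels, ".sam")),
                          config$tissue_labels)
  )
  write_genome(gen$genome, paths$genome)
  write_features(gen$features, paths$features, genome = gen$genome)
  write_truth(truth, paths$truth)
  aln <- list()
  for (t in config$tissue_labels) {
    aln[[t]] <- simulate_reads(gen$genome, truth, config, t,
                               path = paths$sam[[t]], features = gen$features)
  }
  invisible(list(genome = gen$genome, features = gen$features, truth = truth,
                 alignments = aln, paths = paths, config = config))
}
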