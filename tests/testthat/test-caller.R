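test_that("calling thresholds are applied exactly", {
  genome <- plastome(strrep("ACGT", 50L))
  # position 2 is a C on this genome
  low_cov <- make_pileup(2L, "C", count_C = 4L, count_T = 4L)
  expect_equal(nrow(call_edits(low_cov, genome)), 0L)  # depth 8 < 10

  ok <- make_pileup(2L, "C", count_C = 93L, count_T = 7L)
  out <- call_edits(ok, genome)
  expect_equal(nrow(out), 1L)
  expect_equal(out$edit_type, "C_to_U")
  expect_equal(out$efficiency, 0.07)
  expect_equal(out$efficiency_class, "poor")
  expect_identical(out$transcript_strand, "unassigned")

  # count below min_count
  one_read <- make_pileup(2L, "C", count_C = 19L, count_T = 1L)
  expect_equal(nrow(call_edits(one_read, genome)), 0L)
  # frequency below 5%
  low_freq <- make_pileup(2L, "C", count_C = 97L, count_T = 3L)
  expect_equal(nrow(call_edits(low_freq, genome)), 0L)
  # empty pileup
  expect_equal(nrow(call_edits(ok[0L, ], genome)), 0L)
})

test_that("all four reference bases map to their unique conversion", {
  genome <- plastome(paste0("CTGA", strrep("ACGT", 10L)))
  pu <- rbind(make_pileup(1L, "C", count_C = 50L, count_T = 50L),
              make_pileup(2L, "T", count_T = 50L, count_C = 50L),
              make_pileup(3L, "G", count_G = 50L, count_A = 50L),
              make_pileup(4L, "A", count_A = 50L, count_G = 50L))
  out <- call_edits(pu, genome)
  expect_equal(out$edit_type, c("C_to_U", "U_to_C", "C_to_U", "U_to_C"))
  expect_equal(out$orientation, c("+", "+", "-", "-"))
  expect_true(all(out$efficiency == 0.5))
})

test_that("feature strand restricts the evaluated orientation", {
  genome <- plastome(strrep("ACGT", 50L))
  feats <- feature_table("g1", "CDS", 1L, 12L, "+", 0L, 1L)
  # ref G with A reads is C_to_U on '-', not allowed inside a '+' CDS
  pu <- make_pileup(3L, "G", count_G = 50L, count_A = 50L)
  expect_equal(nrow(call_edits(pu, genome, feats)), 0L)
  # the same column outside the feature is called with unassigned strand
  pu2 <- make_pileup(15L, "G", count_G = 50L, count_A = 50L)
  out <- call_edits(pu2, genome, feats)
  expect_equal(out$transcript_strand, "unassigned")
  # and a strand-consistent conversion inside the CDS is called as '+'
  pu3 <- make_pileup(2L, "C", count_C = 50L, count_T = 50L)
  out3 <- call_edits(pu3, genome, feats)
  expect_equal(out3$transcript_strand, "+")
})

test_that("efficiency classification follows the five-bin scheme", {
  expect_equal(classify_efficiency(0.64), "high")
  expect_equal(classify_efficiency(0.42), "medium")
  expect_equal(classify_efficiency(0.71), "high")
  expect_equal(classify_efficiency(c(0.07, 0.12, 0.20)),
               rep("poor", 3L))
  # boundary convention: lower-exclusive, upper-inclusive
  expect_equal(classify_efficiency(c(0.91, 0.90, 0.60, 0.40, 0.20, 0.05)),
               c("full", "high", "medium", "low", "poor", "poor"))
  expect_error(classify_efficiency(0.04), "calling threshold")
})

test_that("sites in homopolymer runs are flagged and excluded downstream", {
  genome <- plastome(paste0(strrep("ACGT", 10L), "CCCCCC", strrep("ACGT", 10L)))
  expect_equal(nrow(genome$homopolymer), 1L)
  inrun <- 43L  # third C of the run
  pu <- rbind(make_pileup(inrun, "C", count_C = 50L, count_T = 50L),
              make_pileup(2L, "C", count_C = 50L, count_T = 50L))
  out <- call_edits(pu, genome)
  expect_equal(nrow(out), 2L)
  expect_true(out$homopolymer_flag[out$position == inrun])
  expect_false(out$homopolymer_flag[out$position == 2L])
  # border position (distance 1 from the run) is flagged too
  pu2 <- make_pileup(40L, "T", count_T = 50L, count_C = 50L)
  expect_true(call_edits(pu2, genome)$homopolymer_flag)
  # flagged sites are absent from the summary accounting
  feats <- feature_table()
  ann <- lapply(list(leaf = out, flower = out), annotate_edits,
                features = feats, genome = genome)
  s <- summarize_edits(ann, genome)
  expect_equal(s$counts$total[s$counts$category == "total"], 1L)
})

test_that("raising any threshold never increases the number of calls", {
  cfg <- small_config()
  sim <- simulate_dataset(cfg, tempfile("mono"))
  p <- build_pileup(filter_alignments(sim$alignments$leaf), sim$genome)
  base <- nrow(call_edits(p, sim$genome, sim$features))
  for (cp in list(call_params(min_coverage = 25L),
                  call_params(min_count = 8L),
                  call_params(min_frequency = 0.30))) {
    expect_lte(nrow(call_edits(p, sim$genome, sim$features, cp)), base)
  }
})

test_that("calls are invariant under genome reverse-complement mirroring", {
  cfg <- sim_config(genome_length = 2000L, n_genes = 2L, intron_genes = 0L,
                    trna_genes = 0L, read_length = 60L, mean_coverage = 60,
                    error_rate = 0, n_edits = 8L, seed = 21L,
                    homopolymer_truth_sites = 0L)
  sim <- simulate_dataset(cfg, tempfile("mir"))
  aln <- filter_alignments(sim$alignments$leaf)
  calls <- call_edits(build_pileup(aln, sim$genome), sim$genome, sim$features)
  mir <- mirror_dataset(sim$genome, sim$features, aln)
  calls2 <- call_edits(build_pileup(mir$aln, mir$genome), mir$genome,
                       mir$features)
  expect_equal(nrow(calls), nrow(calls2))
  m <- calls2[order(-calls2$position), ]
  expect_equal(sim$genome$length - m$position + 1L, calls$position)
  expect_equal(m$edit_type, calls$edit_type)
  expect_equal(m$efficiency, calls$efficiency)
  flip <- c("+" = "-", "-" = "+")
  expect_equal(unname(flip[m$orientation]), calls$orientation)
})

test_that("caller matches the exhaustive recount oracle", {
  cfg <- sim_config(genome_length = 2000L, n_genes = 2L, intron_genes = 1L,
                    trna_genes = 0L, read_length = 60L, mean_coverage = 60,
                    error_rate = 0.005, n_edits = 10L, seed = 17L)
  sim <- simulate_dataset(cfg, tempfile("corc"))
  for (t in cfg$tissue_labels) {
    p <- build_pileup(filter_alignments(sim$alignments[[t]]), sim$genome)
    mine <- call_edits(p, sim$genome, sim$features)
    ref <- naive_call(p, sim$genome, sim$features, call_params())
    expect_equal(mine[, names(ref)], ref, info = t)
  }
})

test_that("planted edits are recovered with accurate efficiencies", {
  cfg <- sim_config(genome_length = 4000L, n_genes = 4L, intron_genes = 1L,
                    trna_genes = 1L, read_length = 100L, mean_coverage = 200,
                    error_rate = 0, n_edits = 30L, seed = 19L,
                    efficiency_range = c(0.15, 0.95),
                    tissue_specific_sites = 0L,
                    forced_differential_sites = 0L,
                    homopolymer_truth_sites = 0L, tissue_labels = "leaf")
  sim <- simulate_dataset(cfg, tempfile("rec"))
  p <- build_pileup(filter_alignments(sim$alignments$leaf), sim$genome)
  calls <- call_edits(p, sim$genome, sim$features)
  m <- match(sim$truth$position, calls$position)
  expect_true(all(!is.na(m)))
  err <- abs(calls$efficiency[m] - sim$truth$eff_leaf)
  se <- sqrt(sim$truth$eff_leaf * (1 - sim$truth$eff_leaf) / calls$depth[m])
  expect_true(all(err <= 3 * se))
  # no false positives at error_rate 0
  expect_equal(sort(calls$position[!calls$homopolymer_flag]),
               sort(sim$truth$position))
})
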