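test_that("feature assignment labels CDS, non-CDS and intergenic sites", {
  tg <- toy_gene(c("ATG", "TCA", "GGT", "TAA"))
  calls <- data.frame(position = c(5L, tg$gstart + 4L, tg$gend + 5L),
                      transcript_strand = c("unassigned", "+", "unassigned"),
                      orientation = c("+", "+", "+"),
                      edit_type = "C_to_U", edited_count = 10L, depth = 100L,
                      efficiency = 0.1, efficiency_class = "poor",
                      homopolymer_flag = FALSE, stringsAsFactors = FALSE)
  out <- assign_feature(calls, tg$features, tg$genome)
  expect_equal(out$feature_class, c("IGS", "CDS", "IGS"))
  expect_equal(out$site_label[2L], "geneX-5")
  expect_equal(out$cds_position[2L], 5L)

  # tRNA sites are labelled by genomic position
  g <- plastome(strrep("ACGT", 30L))
  ft <- feature_table("trnM", "tRNA", 21L, 92L, "+", NA, 1L)
  calls$position <- c(5L, 30L, 100L)
  out2 <- assign_feature(calls, ft, g)
  expect_equal(out2$feature_class[2L], "tRNA")
  expect_equal(out2$site_label[2L], "trnM (30)")
})

test_that("spliced CDS offsets are exon-structure independent", {
  # cds_position 56 of a minus-strand two-exon gene
  codons <- c("ATG", rep("GCA", 28L), "TAA")  # 90 nt CDS
  tg <- toy_gene(codons, strand = "-", intron_after = 33L)
  spl <- plastedit:::spliced_cds(tg$features, tg$genome, "geneX")
  expect_equal(nchar(spl), 90L)
  expect_equal(spl, paste(codons, collapse = ""))
  # walk: position 56 in transcript space -> find its genomic position,
  # then confirm the offset computation inverts it
  hit <- NA_integer_
  for (p in tg$gstart:tg$gend) {
    off <- plastedit:::cds_offset(tg$features, "geneX", p)
    if (!is.na(off) && off == 56L) hit <- p
  }
  expect_false(is.na(hit))
  expect_equal(plastedit:::cds_offset(tg$features, "geneX", hit), 56L)
})

test_that("codon consequences match whole-CDS translation", {
  set.seed(7)
  nonstop <- setdiff(plastedit:::all_codons(), c("TAA", "TAG", "TGA"))
  for (rep_i in 1:20) {
    codons <- c("ATG", sample(nonstop, 30L, replace = TRUE), "TAA")
    cds <- paste(codons, collapse = "")
    # pick a random C in the CDS body (avoid the stop codon)
    cpos <- which(strsplit(cds, "")[[1L]] == "C")
    cpos <- cpos[cpos <= length(codons) * 3L - 3L]
    if (!length(cpos)) next
    p <- sample(cpos, 1L)
    tg <- toy_gene(codons)
    cons <- codon_consequence(tg$features, tg$genome, "geneX", p, "C_to_U")
    edited_cds <- cds
    substr(edited_cds, p, p) <- "T"
    aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    aa_ed <- as.character(Biostrings::translate(Biostrings::DNAString(edited_cds)))
    ndiff <- sum(strsplit(aa_ref, "")[[1L]] != strsplit(aa_ed, "")[[1L]])
    if (cons$effect == "synonymous") {
      expect_equal(ndiff, 0L)
    } else {
      expect_equal(ndiff, 1L)
      ci <- cons$codon_index
      expect_equal(substr(aa_ed, ci, ci), cons$edited_aa)
    }
    expect_equal((p - 1L) %% 3L + 1L, cons$codon_position)
  }
})

test_that("start and stop creation are recognised", {
  # ACG initiation codon edited at codon position 2 becomes AUG
  tg <- toy_cds_with("ACG", 1L, start_codon = "ACG")
  cons <- codon_consequence(tg$features, tg$genome, "geneX", 2L, "C_to_U")
  expect_equal(cons$effect, "start_created")
  expect_equal(cons$ref_codon, "ACG")
  expect_equal(cons$edited_codon, "AUG")
  expect_equal(cons$hydropathy_delta, 0)
  # internal ACG -> AUG is plain nonsynonymous (Thr -> Met)
  tg2 <- toy_cds_with("ACG", 5L)
  cons2 <- codon_consequence(tg2$features, tg2$genome, "geneX", 14L, "C_to_U")
  expect_equal(cons2$effect, "nonsynonymous")
  # CAA -> UAA internal stop creation
  tg3 <- toy_cds_with("CAA", 7L)
  cons3 <- codon_consequence(tg3$features, tg3$genome, "geneX", 19L, "C_to_U")
  expect_equal(cons3$effect, "stop_created")
  expect_equal(cons3$edited_aa, "*")
  expect_equal(cons3$hydropathy_delta, 0)
})

test_that("consequences work identically on minus-strand genes", {
  tg <- toy_cds_with("ACA", 19L, strand = "-")
  cons <- codon_consequence(tg$features, tg$genome, "geneX", 56L, "C_to_U")
  expect_equal(cons$ref_codon, "ACA")
  expect_equal(cons$edited_codon, "AUA")
  expect_equal(cons$ref_aa, "T")
  expect_equal(cons$edited_aa, "I")
  expect_gt(cons$hydropathy_delta, 0)
})

test_that("out-of-range CDS positions raise an annotation error", {
  tg <- toy_cds_with("TCA", 3L, n_codons = 10L)
  expect_error(codon_consequence(tg$features, tg$genome, "geneX", 31L),
               "annotation error")
  expect_error(codon_consequence(tg$features, tg$genome, "geneX", c(4L, 8L)),
               "single codon")
})

test_that("nearest-neighbour context is computed in transcript orientation", {
  # constructed plus-strand sites with T before and A after each edited C
  g <- plastome(paste0("GG", strrep("TCAGG", 10L), "GG"))
  pos <- 2L + seq(2L, by = 5L, length.out = 10L)  # the C of each TCA
  ann <- data.frame(position = pos, orientation = "+",
                    feature_class = "IGS", stringsAsFactors = FALSE)
  ctx <- neighbor_context(ann, g)
  up_u <- ctx$frequency[ctx$offset == "-1" & ctx$base == "U"]
  down_a <- ctx$frequency[ctx$offset == "+1" & ctx$base == "A"]
  expect_equal(up_u, 1)
  expect_equal(down_a, 1)
  expect_equal(sum(ctx$frequency[ctx$offset == "-1"]), 1)

  # single site: point mass
  ctx1 <- neighbor_context(ann[1L, ], g)
  expect_true(all(ctx1$frequency %in% c(0, 1)))

  # minus-strand orientation complements and swaps the neighbours:
  # plus-strand T G A reads U before / A after on the minus strand
  g2 <- plastome("GGTGAGG")
  ann2 <- data.frame(position = 4L, orientation = "-",
                     feature_class = "IGS", stringsAsFactors = FALSE)
  ctx2 <- neighbor_context(ann2, g2)
  expect_equal(ctx2$frequency[ctx2$offset == "-1" & ctx2$base == "U"], 1)
  expect_equal(ctx2$frequency[ctx2$offset == "+1" & ctx2$base == "A"], 1)

  # sites at the genome edge are excluded with a message
  ann3 <- rbind(ann, data.frame(position = 1L, orientation = "+",
                                feature_class = "IGS"))
  expect_message(neighbor_context(ann3, g), "excluded 1")
})

test_that("context of randomly placed sites matches the dinucleotide background", {
  cfg <- sim_config(genome_length = 10000L, n_genes = 0L, trna_genes = 0L,
                    intron_genes = 0L, n_edits = 400L, seed = 23L,
                    homopolymer_truth_sites = 0L,
                    tissue_specific_sites = 0L,
                    forced_differential_sites = 0L, u_to_c_fraction = 0)
  gen <- generate_genome(cfg)
  truth <- plant_edits(gen$genome, gen$features, cfg)
  ann <- data.frame(position = truth$position, orientation = truth$strand,
                    feature_class = "IGS", stringsAsFactors = FALSE)
  ctx <- neighbor_context(ann, gen$genome)
  # background: distribution of transcript-strand bases next to eligible Cs
  chars <- strsplit(gen$genome$sequence, "", fixed = TRUE)[[1L]]
  mask <- plastedit:::homopolymer_mask(gen$genome$homopolymer,
                                       gen$genome$length, 1L)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ok <- which(!mask)
  ok <- ok[ok > 1L & ok < gen$genome$length]
  up <- c(chars[ok[chars[ok] == "C"] - 1L],
          comp[chars[ok[chars[ok] == "G"] + 1L]])
  bg <- as.numeric(table(factor(up, levels = c("A", "C", "G", "T"))))
  bg <- bg / sum(bg)
  obs <- ctx$frequency[ctx$offset == "-1"][match(c("A", "C", "G", "U"),
                                                 ctx$base[ctx$offset == "-1"])]
  se <- sqrt(bg * (1 - bg) / nrow(ann))
  expect_true(all(abs(obs - bg) < 4 * se + 0.01))
})

test_that("window extraction is oriented, truncation-aware and editable", {
  g <- plastome(paste0(strrep("G", 40L), "C", strrep("A", 40L)))
  w0 <- extract_window(g, 41L, "+", 0L, 0L)
  expect_equal(w0$sequence, "C")
  expect_equal(w0$edited_sequence, "T")
  w <- extract_window(g, 41L, "+", 30L, 10L)
  expect_equal(nchar(w$sequence), 41L)
  expect_equal(w$site_index, 31L)
  expect_false(w$truncated)
  # minus-strand window is the reverse complement of the plus-strand slice
  g2 <- plastome(paste0(strrep("T", 10L), "G", strrep("CTAG", 10L)))
  wm <- extract_window(g2, 11L, "-", 5L, 5L, "C_to_U")
  plus_slice <- substring(g2$sequence, 6L, 16L)
  expect_equal(wm$sequence, revcomp(plus_slice))
  expect_equal(substr(wm$sequence, wm$site_index, wm$site_index), "C")
  # truncation at the genome end
  wt <- extract_window(g, 41L, "+", 60L, 60L)
  expect_true(wt$truncated)
})
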