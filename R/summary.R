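#' Set-algebra helpers for two-tissue edit accounting
#'
#' The bookkeeping identities a two-tissue editing survey rests on:
#' the union of sites called in either tissue is
#' `n_a + n_b - n_common`; conversely the common count implied by two
#' per-tissue counts and their union is `n_a + n_b - n_total`; a total can
#' also be assembled from the common count plus the two tissue-specific
#' counts; and the newly discovered count is the total minus the number of
#' previously known sites recovered.
#'
#' @param n_a,n_b Per-tissue site counts.
#' @param n_common Sites called in both tissues.
#' @param n_total Union count.
#' @param n_a_specific,n_b_specific Sites exclusive to each tissue.
#' @param n_known Previously reported sites contained in the total.
#' @return An integer count.
#' @name set-accounting
NULL

#' @rdname set-accounting
#' @export
count_union <- function(n_a, n_b, n_common) n_a + n_b - n_common

#' @rdname set-accounting
#' @export
count_common <- function(n_a, n_b, n_total) n_a + n_b - n_total

#' @rdname set-accounting
#' @export
count_from_specific <- function(n_common, n_a_specific, n_b_specific)
  n_common + n_a_specific + n_b_specific

#' @rdname set-accounting
#' @export
count_new <- function(n_total, n_known) n_total - n_known

#' Percentage share with printed rounding
#'
#' @param k Numerator count.
#' @param n Denominator count.
#' @param digits Decimal places to round to (0 for whole-percent shares,
#'   1 for one-decimal shares, 2 for per-nucleotide rates).
#' @return `round(100 * k / n, digits)`.
#' @export
share_pct <- function(k, n, digits = 1) round(100 * k / n, digits)

site_keys <- function(x) paste(x$position, x$orientation, x$edit_type)

category_counts <- function(ann) {
  cds <- ann$feature_class == "CDS" & !is.na(ann$codon_position)
  c(
    total = nrow(ann),
    c_to_u = sum(ann$edit_type == "C_to_U"),
    u_to_c = sum(ann$edit_type == "U_to_C"),
    protein_coding = sum(ann$feature_class == "CDS"),
    codon_pos_1 = sum(cds & ann$codon_position == 1L),
    codon_pos_2 = sum(cds & ann$codon_position == 2L),
    codon_pos_3 = sum(cds & ann$codon_position == 3L),
    start_created = sum(cds & ann$effect == "start_created"),
    stop_created = sum(cds & ann$effect == "stop_created"),
    nonsynonymous = sum(cds & ann$effect == "nonsynonymous"),
    synonymous = sum(cds & ann$effect == "synonymous"),
    noncoding = sum(ann$feature_class != "CDS"),
    tRNA = sum(ann$feature_class == "tRNA"),
    rRNA = sum(ann$feature_class == "rRNA"),
    intron = sum(ann$feature_class == "intron"),
    IGS = sum(ann$feature_class == "IGS")
  )
}

#' Summarise an editing survey across tissues
#'
#' Builds the per-tissue / common / total accounting table over edit
#' categories (conversion type, codon position, start/stop creation,
#' synonymy, non-coding feature classes) together with the derived
#' percentages: efficiency-class shares per tissue (1 decimal),
#' codon-position and substitution shares of the codon-involving total
#' (whole percent; start/stop-creating edits count as nonsynonymous there),
#' and edits per genome nucleotide as a percentage (2 decimals).
#' Homopolymer-flagged calls are excluded throughout.
#'
#' @param annotated_per_tissue Named list of annotated call data frames
#'   from [annotate_edits()].
#' @param genome A [plastome()].
#' @param differential Optional differential table from [merge_tissues()];
#'   adds up/down/total differential counts.
#' @param known_positions Optional integer vector of previously reported
#'   editing positions; adds a newly-discovered count.
#' @param diff_threshold Threshold passed to [differential_counts()].
#' @return Object of class `edit_summary`: list with elements `counts`
#'   (data frame, one row per category), `percentages`, `differential`,
#'   `n_known_recovered`, `n_new`.
#' @export
summarize_edits <- function(annotated_per_tissue, genome,
                            differential = NULL, known_positions = NULL,
                            diff_threshold = 0.20) {
  tissues <- names(annotated_per_tissue)
  clean <- lapply(annotated_per_tissue, function(x)
    x[!x$homopolymer_flag, , drop = FALSE])
  keys <- lapply(clean, site_keys)
  union_df <- do.call(rbind, clean)
  union_df <- union_df[!duplicated(site_keys(union_df)), , drop = FALSE]
  common_keys <- Reduce(intersect, keys)
  common_df <- union_df[site_keys(union_df) %in% common_keys, , drop = FALSE]

  cols <- list()
  for (t in tissues) cols[[t]] <- category_counts(clean[[t]])
  cols[["common"]] <- category_counts(common_df)
  cols[["total"]] <- category_counts(union_df)
  counts <- data.frame(category = names(cols[[1L]]),
                       do.call(cbind, lapply(cols, as.integer)),
                       stringsAsFactors = FALSE, check.names = FALSE)

  pct <- list()
  for (t in tissues) {
    cl <- clean[[t]]$efficiency_class
    tab <- table(factor(cl, levels = c("full", "high", "medium", "low", "poor")))
    pct[[paste0("efficiency_class_", t)]] <- data.frame(
      class = names(tab), count = as.integer(tab),
      pct = share_pct(as.integer(tab), max(1L, sum(tab)), 1),
      stringsAsFactors = FALSE)
  }
  tot <- cols[["total"]]
  codon_total <- tot[["codon_pos_1"]] + tot[["codon_pos_2"]] + tot[["codon_pos_3"]]
  if (codon_total > 0L) {
    pct$codon_position <- c(
      pos1 = share_pct(tot[["codon_pos_1"]], codon_total, 0),
      pos2 = share_pct(tot[["codon_pos_2"]], codon_total, 0),
      pos3 = share_pct(tot[["codon_pos_3"]], codon_total, 0))
    nonsyn_incl <- tot[["nonsynonymous"]] + tot[["start_created"]] +
      tot[["stop_created"]]
    pct$substitution <- c(
      nonsynonymous = share_pct(nonsyn_incl, codon_total, 0),
      synonymous = share_pct(tot[["synonymous"]], codon_total, 0))
  }
  pct$edits_per_nucleotide <- share_pct(tot[["total"]], genome$length, 2)

  diff <- NULL
  if (!is.null(differential) && "delta" %in% names(differential))
    diff <- differential_counts(differential$delta, diff_threshold)

  n_known <- n_new <- NULL
  if (!is.null(known_positions)) {
    n_known <- sum(unique(union_df$position) %in% known_positions)
    n_new <- count_new(tot[["total"]], n_known)
  }

  structure(list(counts = counts, percentages = pct, differential = diff,
                 n_known_recovered = n_known, n_new = n_new,
                 tissues = tissues, genome_length = genome$length),
            class = "edit_summary")
}

#' @export
print.edit_summary <- function(x, ...) {
  cat("Editing-site summary (", paste(x$tissues, collapse = " / "),
      "; homopolymer-flagged sites excluded)\n\n", sep = "")
  print(x$counts, row.names = FALSE)
  cat(sprintf("\nEdits per genome nucleotide: %.2f%%\n",
              x$percentages$edits_per_nucleotide))
  if (!is.null(x$percentages$codon_position)) {
    cp <- x$percentages$codon_position
    cat(sprintf("Codon-position shares: 1st %g%%, 2nd %g%%, 3rd %g%%\n",
                cp[["pos1"]], cp[["pos2"]], cp[["pos3"]]))
    sb <- x$percentages$substitution
    cat(sprintf("Substitutions: %g%% nonsynonymous, %g%% synonymous\n",
                sb[["nonsynonymous"]], sb[["synonymous"]]))
  }
  for (t in x$tissues) {
    ec <- x$percentages[[paste0("efficiency_class_", t)]]
    cat(sprintf("Efficiency classes in %s: %s\n", t,
                paste(sprintf("%s %d (%.1f%%)", ec$class, ec$count, ec$pct),
                      collapse = ", ")))
  }
  if (!is.null(x$differential))
    cat(sprintf("Differential edits: %d (%d up, %d down)\n",
                x$differential$total, x$differential$up, x$differential$down))
  if (!is.null(x$n_new))
    cat(sprintf("Newly discovered edits: %d (of %d total; %d previously known)\n",
                x$n_new, x$counts$total[x$counts$category == "total"],
                x$n_known_recovered))
  invisible(x)
}
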