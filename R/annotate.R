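#' Kyte-Doolittle hydropathy scale
#'
#' Named numeric vector of hydropathy values per amino-acid letter; larger
#' values are more hydrophobic.
#'
#' @export
KYTE_DOOLITTLE <- c(
  I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
  H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
)

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  if (any(is.na(aa))) stop("invalid codon: ", paste(codon[is.na(aa)], collapse = ","))
  unname(aa)
}

as_rna <- function(x) chartr("T", "U", x)

#' Assign called edits to genomic features
#'
#' Each site is assigned to the unique overlapping feature; positions in no
#' feature are intergenic spacer (`IGS`). CDS sites get their 1-based
#' offset within the spliced CDS, computed by walking exons in transcript
#' orientation, and a `<gene>-<cds_position>` site label; all other sites
#' are labelled by genomic position, with flanking gene names appended for
#' IGS sites.
#'
#' @param calls Data frame from [call_edits()].
#' @param features A [feature_table()].
#' @param genome A [plastome()] (used for IGS flank lookup bounds).
#' @return `calls` with added columns `feature_class`, `feature_id`,
#'   `cds_position`, `site_label`.
#' @export
assign_feature <- function(calls, features, genome) {
  n <- nrow(calls)
  ann <- position_annotation(features, genome$length)
  cls <- ann$class[calls$position]
  gene <- ann$gene[calls$position]
  cdspos <- rep(NA_integer_, n)
  label <- character(n)
  for (i in seq_len(n)) {
    if (!is.na(gene[i]) && cls[i] == "CDS") {
      cdspos[i] <- cds_offset(features, gene[i], calls$position[i])
      label[i] <- sprintf("%s-%d", gene[i], cdspos[i])
    } else if (!is.na(gene[i])) {
      label[i] <- sprintf("%s (%d)", gene[i], calls$position[i])
    } else {
      fl <- igs_flanks(features, calls$position[i])
      label[i] <- if (nzchar(fl)) sprintf("%s (%d)", fl, calls$position[i])
                  else as.character(calls$position[i])
    }
  }
  calls$feature_class <- cls
  calls$feature_id <- ifelse(is.na(gene), "", gene)
  calls$cds_position <- cdspos
  calls$site_label <- label
  calls
}

igs_flanks <- function(features, position) {
  if (!nrow(features)) return("")
  left <- features[features$end < position, , drop = FALSE]
  right <- features[features$start > position, , drop = FALSE]
  ln <- if (nrow(left)) left$feature_id[which.max(left$end)] else ""
  rn <- if (nrow(right)) right$feature_id[which.min(right$start)] else ""
  if (nzchar(ln) && nzchar(rn)) paste0(ln, "-", rn) else paste0(ln, rn)
}

#' Codon consequence of an edit within a CDS
#'
#' Translates the reference and edited codons under the standard genetic
#' code and classifies the effect: `start_created` when the edit falls in
#' codon 1 of a CDS whose annotated initiation codon is not ATG and the
#' edited codon becomes ATG (e.g. ACG to AUG); `stop_created` when the
#' edited codon is a stop and the reference codon is not; otherwise
#' `synonymous` or `nonsynonymous` by amino-acid identity. The hydropathy
#' change is the Kyte-Doolittle value of the edited residue minus that of
#' the reference residue (0 for start/stop cases).
#'
#' Several positions within the same codon may be given to annotate a
#' co-edited codon jointly; `codon_position` is then `NA`.
#'
#' @param features A [feature_table()].
#' @param genome A [plastome()].
#' @param gene Gene identifier of an annotated CDS.
#' @param cds_position 1-based position(s) within the spliced CDS; when
#'   more than one, all must fall in the same codon.
#' @param edit_type `"C_to_U"` or `"U_to_C"` (recycled across positions).
#' @return One-row data frame with columns `gene`, `cds_position`,
#'   `codon_index`, `codon_position`, `ref_codon`, `edited_codon` (RNA
#'   alphabet), `ref_aa`, `edited_aa`, `effect`, `hydropathy_delta`.
#' @export
codon_consequence <- function(features, genome, gene, cds_position,
                              edit_type = "C_to_U") {
  stopifnot(length(cds_position) >= 1L)
  edit_type <- rep_len(edit_type, length(cds_position))
  spliced <- spliced_cds(features, genome, gene)
  if (any(cds_position < 1L) || any(cds_position > nchar(spliced)))
    stop("annotation error: cds_position beyond spliced CDS length (",
         nchar(spliced), ") for gene ", gene)
  ci <- unique((cds_position - 1L) %/% 3L + 1L)
  if (length(ci) != 1L)
    stop("co-edited positions must fall within a single codon")
  ref_codon <- substr(spliced, 3L * ci - 2L, 3L * ci)
  edited_codon <- ref_codon
  for (k in seq_along(cds_position)) {
    cp <- (cds_position[k] - 1L) %% 3L + 1L
    have <- substr(edited_codon, cp, cp)
    want <- if (edit_type[k] == "C_to_U") "C" else "T"
    ref_have <- substr(ref_codon, cp, cp)
    if (ref_have != want)
      stop(sprintf("annotation error: %s edit at %s cds position %d but reference base is %s",
                   edit_type[k], gene, cds_position[k], ref_have))
    substr(edited_codon, cp, cp) <- if (edit_type[k] == "C_to_U") "T" else "C"
  }
  ref_aa <- translate_codon(ref_codon)
  edited_aa <- translate_codon(edited_codon)
  init_codon <- substr(spliced, 1L, 3L)
  effect <- if (ci == 1L && init_codon != "ATG" && edited_codon == "ATG") {
    "start_created"
  } else if (edited_aa == "*" && ref_aa != "*") {
    "stop_created"
  } else if (ref_aa == edited_aa) {
    "synonymous"
  } else {
    "nonsynonymous"
  }
  hydro <- if (effect %in% c("start_created", "stop_created") ||
               ref_aa == "*" || edited_aa == "*") 0
           else unname(KYTE_DOOLITTLE[edited_aa] - KYTE_DOOLITTLE[ref_aa])
  data.frame(
    gene = gene,
    cds_position = paste(cds_position, collapse = "+"),
    codon_index = ci,
    codon_position = if (length(cds_position) == 1L)
      (cds_position - 1L) %% 3L + 1L else NA_integer_,
    ref_codon = as_rna(ref_codon),
    edited_codon = as_rna(edited_codon),
    ref_aa = ref_aa,
    edited_aa = edited_aa,
    effect = effect,
    hydropathy_delta = hydro,
    stringsAsFactors = FALSE
  )
}

#' Annotate called edits with features and codon consequences
#'
#' Convenience wrapper: runs [assign_feature()] and, for CDS sites, adds
#' the [codon_consequence()] columns.
#'
#' @inheritParams assign_feature
#' @return Annotated calls data frame.
#' @export
annotate_edits <- function(calls, features, genome) {
  out <- assign_feature(calls, features, genome)
  cons_cols <- c("codon_index", "codon_position", "ref_codon", "edited_codon",
                 "ref_aa", "edited_aa", "effect")
  for (cc in cons_cols) out[[cc]] <- rep(NA, nrow(out))
  out$hydropathy_delta <- rep(NA_real_, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (out$feature_class[i] == "CDS" && !is.na(out$cds_position[i])) {
      cons <- codon_consequence(features, genome, out$feature_id[i],
                                out$cds_position[i], out$edit_type[i])
      for (cc in cons_cols) out[[cc]][i] <- cons[[cc]]
      out$hydropathy_delta[i] <- cons$hydropathy_delta
    }
  }
  out$codon_index <- as.integer(out$codon_index)
  out$codon_position <- as.integer(out$codon_position)
  out
}

#' Nearest-neighbour context of editing sites
#'
#' Tabulates, separately for protein-coding (CDS) and non-protein-coding
#' sites, the frequency of each nucleotide immediately 5' (-1) and 3' (+1)
#' of the edited position in transcript orientation; T is reported as U.
#' Sites lacking a neighbour at the genome ends are excluded with a
#' message.
#'
#' @param annotated Annotated calls from [annotate_edits()] (needs
#'   `orientation` and `feature_class` columns).
#' @param genome A [plastome()].
#' @return Data frame with columns `group` (`protein_coding` /
#'   `non_coding`), `offset` (`-1` / `+1`), `base` (A/C/G/U), `frequency`;
#'   frequencies sum to 1 within each group-offset stratum.
#' @export
neighbor_context <- function(annotated, genome) {
  L <- genome$length
  chars <- genome_chars(genome)
  at_edge <- annotated$position <= 1L | annotated$position >= L
  if (any(at_edge))
    message(sprintf("neighbor_context: excluded %d site(s) at genome ends",
                    sum(at_edge)))
  x <- annotated[!at_edge, , drop = FALSE]
  if (!nrow(x)) return(data.frame(group = character(), offset = character(),
                                  base = character(), frequency = numeric(),
                                  stringsAsFactors = FALSE))
  minus <- x$orientation == "-"
  up <- ifelse(minus, complement_base(chars[x$position + 1L]),
               chars[x$position - 1L])
  down <- ifelse(minus, complement_base(chars[x$position - 1L]),
                 chars[x$position + 1L])
  group <- ifelse(x$feature_class == "CDS", "protein_coding", "non_coding")
  res <- list()
  for (g in unique(group)) {
    for (off in c("-1", "+1")) {
      b <- if (off == "-1") up[group == g] else down[group == g]
      tab <- table(factor(b, levels = DNA_BASES))
      res[[length(res) + 1L]] <- data.frame(
        group = g, offset = off, base = as_rna(DNA_BASES),
        frequency = as.numeric(tab) / sum(tab), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Extract an oriented sequence window around an editing site
#'
#' Returns the transcript-strand sequence covering `upstream` bases 5' and
#' `downstream` bases 3' of the site, in both unedited and edited form.
#' Windows exceeding the genome bounds are truncated and flagged.
#'
#' @param genome A [plastome()].
#' @param position 1-based genomic position of the site.
#' @param orientation `"+"` or `"-"`: the transcript strand.
#' @param upstream,downstream Number of flanking bases on each side.
#' @param edit_type `"C_to_U"` or `"U_to_C"`.
#' @return List with `sequence`, `edited_sequence` (DNA alphabet),
#'   `site_index` (1-based index of the edited base within the window) and
#'   `truncated` (logical).
#' @export
extract_window <- function(genome, position, orientation = "+",
                           upstream = 30L, downstream = 10L,
                           edit_type = "C_to_U") {
  L <- genome$length
  if (orientation == "+") {
    lo <- position - upstream; hi <- position + downstream
  } else {
    lo <- position - downstream; hi <- position + upstream
  }
  truncated <- lo < 1L || hi > L
  lo2 <- max(1L, lo); hi2 <- min(L, hi)
  win <- substring(genome$sequence, lo2, hi2)
  idx_plus <- position - lo2 + 1L
  if (orientation == "-") {
    win <- revcomp(win)
    idx <- nchar(win) - idx_plus + 1L
  } else {
    idx <- idx_plus
  }
  edited <- win
  ref_here <- substr(win, idx, idx)
  want <- if (edit_type == "C_to_U") "C" else "T"
  if (ref_here != want)
    stop(sprintf("transcript base at site is %s, inconsistent with %s",
                 ref_here, edit_type))
  substr(edited, idx, idx) <- if (edit_type == "C_to_U") "T" else "C"
  list(sequence = win, edited_sequence = edited, site_index = idx,
       truncated = truncated)
}
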