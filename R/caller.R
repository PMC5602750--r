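#' Edit-calling parameters
#'
#' Thresholds of the low-frequency variant rule used to declare an RNA
#' editing site: minimum coverage 10, minimum edited-read count 2 and
#' minimum edited-read frequency 5%, plus masking of candidate sites inside
#' (or immediately bordering) homopolymer runs of six or more identical
#' bases, where sequencing slippage mimics editing.
#'
#' @param min_coverage Minimum read depth at the position.
#' @param min_count Minimum number of reads carrying the edited base.
#' @param min_frequency Minimum edited-read fraction.
#' @param homopolymer_min_run Run length at and above which a homopolymer
#'   masks candidate sites (6 = runs of more than five).
#' @return List of class `call_params`.
#' @export
call_params <- function(min_coverage = 10L, min_count = 2L,
                        min_frequency = 0.05, homopolymer_min_run = 6L) {
  if (min_coverage < 1L) stop("min_coverage must be >= 1")
  if (min_frequency <= 0 || min_frequency > 1)
    stop("min_frequency must be in (0, 1]")
  structure(list(min_coverage = as.integer(min_coverage),
                 min_count = as.integer(min_count),
                 min_frequency = min_frequency,
                 homopolymer_min_run = as.integer(homopolymer_min_run)),
            class = "call_params")
}

#' Classify editing efficiency into the five-bin scheme
#'
#' Full editing is efficiency above 90%; high partial editing 60--90%;
#' medium partial editing 40--60%; low partial editing 20--40%; poor
#' partial editing 5--20%. Shared bin endpoints are resolved
#' lower-exclusive/upper-inclusive (so 0.90 is high, 0.91 full), with the
#' poor bin closed at 0.05 so that every called site has a class.
#'
#' @param efficiency Numeric vector of efficiencies in `[0.05, 1]`.
#' @return Character vector with values `"full"`, `"high"`, `"medium"`,
#'   `"low"`, `"poor"`.
#' @export
classify_efficiency <- function(efficiency) {
  if (any(is.na(efficiency)) || any(efficiency < 0.05) || any(efficiency > 1))
    stop("efficiency must lie in [0.05, 1]: values below the calling ",
         "threshold have no class")
  as.character(cut(efficiency,
                   breaks = c(0.05, 0.20, 0.40, 0.60, 0.90, 1),
                   labels = c("poor", "low", "medium", "high", "full"),
                   include.lowest = TRUE, right = TRUE))
}

# Each reference plus-strand base admits exactly one C-to-U / U-to-C
# interpretation: C -> T is C-to-U on '+', T -> C is U-to-C on '+',
# G -> A is C-to-U on '-', A -> G is U-to-C on '-'.
CONVERSION_TABLE <- data.frame(
  ref_base = c("C", "T", "G", "A"),
  alt_base = c("T", "C", "A", "G"),
  orientation = c("+", "+", "-", "-"),
  edit_type = c("C_to_U", "U_to_C", "C_to_U", "U_to_C"),
  stringsAsFactors = FALSE
)

#' Call C-to-U and U-to-C editing sites from a pileup
#'
#' Candidate conversions are evaluated in transcript-strand space: inside a
#' stranded feature only the orientation matching the feature strand is
#' considered; outside features the orientation implied by the reference
#' base is used and the site is reported with
#' `transcript_strand = "unassigned"`. A site is emitted iff
#' `depth >= min_coverage`, `edited_count >= min_count` and
#' `edited_count / depth >= min_frequency`. Sites inside, or within 1 bp
#' of, a homopolymer run of at least `homopolymer_min_run` identical bases
#' are kept in the output with `homopolymer_flag = TRUE`; downstream
#' summaries exclude them. Only the C-to-U and U-to-C mismatch classes are
#' ever called; other mismatches contribute to depth only.
#'
#' @param pileup Pileup data frame from [build_pileup()].
#' @param genome A [plastome()].
#' @param features A [feature_table()] (may be empty).
#' @param params A [call_params()].
#' @return Data frame with columns `position`, `transcript_strand`,
#'   `orientation` (the strand used to interpret the conversion),
#'   `edit_type`, `edited_count`, `depth`, `efficiency`,
#'   `efficiency_class`, `homopolymer_flag`, sorted by position.
#' @export
call_edits <- function(pileup, genome, features = feature_table(),
                       params = call_params()) {
  if (nrow(pileup) == 0L) return(empty_calls())
  L <- genome$length
  ann <- position_annotation(features, L)
  runs <- find_homopolymer_runs(genome$sequence, params$homopolymer_min_run)
  mask <- homopolymer_mask(runs, L, pad = 1L)

  conv <- CONVERSION_TABLE[match(pileup$ref_base, CONVERSION_TABLE$ref_base), ]
  alt_count <- integer(nrow(pileup))
  for (b in DNA_BASES) {
    sel <- which(conv$alt_base == b)
    alt_count[sel] <- pileup[[paste0("count_", b)]][sel]
  }
  feat_strand <- ann$strand[pileup$position]
  strand_ok <- is.na(feat_strand) | feat_strand == conv$orientation
  eff <- ifelse(pileup$depth > 0L, alt_count / pileup$depth, 0)
  pass <- strand_ok &
    pileup$depth >= params$min_coverage &
    alt_count >= params$min_count &
    eff >= params$min_frequency
  idx <- which(pass)
  if (!length(idx)) return(empty_calls())
  out <- data.frame(
    position = pileup$position[idx],
    transcript_strand = ifelse(is.na(feat_strand[idx]), "unassigned",
                               feat_strand[idx]),
    orientation = conv$orientation[idx],
    edit_type = conv$edit_type[idx],
    edited_count = alt_count[idx],
    depth = pileup$depth[idx],
    efficiency = eff[idx],
    stringsAsFactors = FALSE
  )
  out$efficiency_class <- ifelse(out$efficiency >= 0.05,
                                 classify_efficiency(pmax(out$efficiency, 0.05)),
                                 NA_character_)
  out$homopolymer_flag <- mask[out$position]
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_calls <- function() {
  data.frame(position = integer(), transcript_strand = character(),
             orientation = character(), edit_type = character(),
             edited_count = integer(), depth = integer(),
             efficiency = numeric(), efficiency_class = character(),
             homopolymer_flag = logical(), stringsAsFactors = FALSE)
}

#' Write called edits as TSV
#'
#' Efficiencies are printed with four decimals.
#'
#' @param calls Data frame from [call_edits()] or [annotate_edits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  out <- calls
  if ("efficiency" %in% names(out))
    out$efficiency <- sprintf("%.4f", out$efficiency)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
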