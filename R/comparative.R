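#' Merge per-tissue edit calls into differential records
#'
#' Takes the union of all called sites (homopolymer-flagged calls are
#' excluded), looks up the raw efficiency of every site in every tissue
#' from the pileups -- so a sub-threshold 3% value is recorded rather than
#' "absent" whenever coverage suffices -- and classifies each site:
#' `common` when called in all tissues, `tissue_specific:<t>` when called
#' only in tissue `t` while every other tissue has adequate coverage but
#' fails the calling thresholds, and `unknown` when the comparison tissue
#' lacks adequate coverage. With exactly two tissues the signed
#' percentage-point difference `delta` (first tissue minus second) is
#' computed on raw efficiencies; a site is differential when both tissues
#' have adequate coverage and `|delta| >= diff_threshold`, with direction
#' `up` (first tissue higher) or `down`.
#'
#' @param calls_per_tissue Named list of call data frames from
#'   [call_edits()]; names are tissue labels, first = direction reference.
#' @param pileups_per_tissue Named list of pileups from [build_pileup()],
#'   same names.
#' @param genome A [plastome()].
#' @param params The [call_params()] used for calling.
#' @param diff_threshold Differential-editing threshold in efficiency
#'   fraction (default 0.20 = 20 percentage points).
#' @return Data frame with one row per union site: `position`,
#'   `orientation`, `edit_type`, one `eff_<tissue>` and `depth_<tissue>`
#'   column per tissue, `status`, and (two tissues only) `delta`,
#'   `differential_flag`, `direction`, `low_coverage`.
#' @export
merge_tissues <- function(calls_per_tissue, pileups_per_tissue, genome,
                          params = call_params(), diff_threshold = 0.20) {
  tissues <- names(calls_per_tissue)
  if (is.null(tissues) || any(!nzchar(tissues)))
    stop("calls_per_tissue must be a named list")
  if (!identical(sort(tissues), sort(names(pileups_per_tissue))))
    stop("calls and pileups must cover the same tissues")
  clean <- lapply(calls_per_tissue, function(x)
    x[!x$homopolymer_flag, , drop = FALSE])
  keys <- unique(do.call(rbind, lapply(clean, function(x)
    x[, c("position", "orientation", "edit_type"), drop = FALSE])))
  if (is.null(keys) || nrow(keys) == 0L)
    return(empty_differential(tissues))
  keys <- keys[order(keys$position), , drop = FALSE]
  rownames(keys) <- NULL
  key_id <- paste(keys$position, keys$orientation, keys$edit_type)

  called <- eff <- depth <- list()
  for (t in tissues) {
    ct <- clean[[t]]
    called[[t]] <- key_id %in% paste(ct$position, ct$orientation, ct$edit_type)
    look <- site_efficiency(pileups_per_tissue[[t]], keys)
    eff[[t]] <- look$efficiency
    depth[[t]] <- look$depth
  }

  out <- keys
  for (t in tissues) {
    out[[paste0("eff_", t)]] <- eff[[t]]
    out[[paste0("depth_", t)]] <- depth[[t]]
  }
  cov_ok <- lapply(tissues, function(t)
    !is.na(depth[[t]]) & depth[[t]] >= params$min_coverage)
  names(cov_ok) <- tissues

  n <- nrow(keys)
  status <- character(n)
  called_mat <- do.call(cbind, called)
  cov_mat <- do.call(cbind, cov_ok)
  for (i in seq_len(n)) {
    cl <- called_mat[i, ]
    if (all(cl)) {
      status[i] <- "common"
    } else if (sum(cl) == 1L) {
      others_ok <- all(cov_mat[i, !cl])
      status[i] <- if (others_ok)
        paste0("tissue_specific:", tissues[which(cl)]) else "unknown"
    } else {
      status[i] <- "partial"
    }
  }
  out$status <- status
  for (t in tissues) out[[paste0("called_", t)]] <- called[[t]]

  if (length(tissues) == 2L) {
    t1 <- tissues[1L]; t2 <- tissues[2L]
    both_ok <- cov_ok[[t1]] & cov_ok[[t2]]
    delta <- eff[[t1]] - eff[[t2]]
    delta[!both_ok] <- NA_real_
    out$delta <- delta
    out$low_coverage <- !both_ok
    out$differential_flag <- both_ok & !is.na(delta) &
      abs(delta) >= diff_threshold
    out$direction <- ifelse(!out$differential_flag, "none",
                            ifelse(delta >= diff_threshold, "up", "down"))
  }
  out
}

# raw efficiency of each (position, orientation, edit_type) key in a pileup
site_efficiency <- function(pileup, keys) {
  idx <- match(keys$position, pileup$position)
  alt <- mapply(function(o, e) {
    CONVERSION_TABLE$alt_base[CONVERSION_TABLE$orientation == o &
                              CONVERSION_TABLE$edit_type == e]
  }, keys$orientation, keys$edit_type, USE.NAMES = FALSE)
  depth <- pileup$depth[idx]
  cnt <- numeric(nrow(keys))
  for (b in DNA_BASES) {
    sel <- which(alt == b)
    cnt[sel] <- pileup[[paste0("count_", b)]][idx[sel]]
  }
  eff <- ifelse(!is.na(depth) & depth > 0L, cnt / depth, NA_real_)
  list(efficiency = eff, depth = ifelse(is.na(depth), 0L, depth))
}

empty_differential <- function(tissues) {
  out <- data.frame(position = integer(), orientation = character(),
                    edit_type = character(), stringsAsFactors = FALSE)
  for (t in tissues) {
    out[[paste0("eff_", t)]] <- numeric()
    out[[paste0("depth_", t)]] <- integer()
  }
  out$status <- character()
  for (t in tissues) out[[paste0("called_", t)]] <- logical()
  if (length(tissues) == 2L) {
    out$delta <- numeric(); out$low_coverage <- logical()
    out$differential_flag <- logical(); out$direction <- character()
  }
  out
}

#' Classify differential-editing deltas
#'
#' Counts up- and down-regulated sites among signed efficiency differences
#' at a given threshold (first tissue minus second).
#'
#' @param deltas Numeric vector of signed efficiency differences; `NA`s
#'   (inadequate coverage) are excluded.
#' @param threshold Differential threshold (default 0.20).
#' @return List with `up`, `down`, `total`.
#' @export
differential_counts <- function(deltas, threshold = 0.20) {
  d <- deltas[!is.na(deltas)]
  up <- sum(d > 0 & d >= threshold)
  down <- sum(d < 0 & d <= -threshold)
  list(up = up, down = down, total = up + down)
}

#' RPKM gene expression from aligned reads
#'
#' Counts a read for a gene when its alignment midpoint falls within the
#' gene's exons (introns are excluded from the exon model), then computes
#' reads per kilobase of exon model per million mapped reads. The library
#' size is the total number of retained mapped reads per tissue. With
#' exactly two tissues a fold-change `ratio` (first / second) is added;
#' genes with zero expression in the denominator tissue get `NA` with
#' `ratio_undefined = TRUE`.
#'
#' @param aln_per_tissue Named list of filtered alignment data frames.
#' @param features A [feature_table()].
#' @return Data frame with columns `gene`, `exon_length`, then per tissue
#'   `count_<t>` and `rpkm_<t>`, plus `ratio` / `ratio_undefined` for the
#'   two-tissue case.
#' @export
compute_rpkm <- function(aln_per_tissue, features) {
  tissues <- names(aln_per_tissue)
  if (is.null(tissues)) stop("aln_per_tissue must be a named list")
  ex <- features[features$feature_class %in% c("CDS", "tRNA", "rRNA"), ,
                 drop = FALSE]
  if (!nrow(ex)) stop("no exon-bearing genes in the feature table")
  genes <- unique(ex$feature_id)
  exlen <- vapply(genes, function(g)
    sum(ex$end[ex$feature_id == g] - ex$start[ex$feature_id == g] + 1L),
    integer(1L))
  if (any(exlen == 0L)) stop("zero-length gene in the feature table")
  exon_ir <- IRanges::IRanges(start = ex$start, end = ex$end)

  out <- data.frame(gene = genes, exon_length = unname(exlen),
                    stringsAsFactors = FALSE)
  for (t in tissues) {
    a <- aln_per_tissue[[t]]
    lib <- nrow(a)
    if (lib == 0L) stop("zero library size for tissue ", t)
    ops <- cigar_op_sums(a$cigar)
    span <- ops[, "M"] + ops[, "D"] + ops[, "N"]
    mid <- a$pos + (span - 1L) %/% 2L
    hits <- IRanges::findOverlaps(IRanges::IRanges(mid, mid), exon_ir)
    hit_gene <- ex$feature_id[S4Vectors::subjectHits(hits)]
    # a read crossing an exon boundary of the same gene counts once
    uniq <- unique(data.frame(q = S4Vectors::queryHits(hits), g = hit_gene))
    cnt <- table(factor(uniq$g, levels = genes))
    out[[paste0("count_", t)]] <- as.integer(cnt)
    out[[paste0("rpkm_", t)]] <-
      as.numeric(cnt) / (unname(exlen) / 1000) / (lib / 1e6)
  }
  if (length(tissues) == 2L) {
    r1 <- out[[paste0("rpkm_", tissues[1L])]]
    r2 <- out[[paste0("rpkm_", tissues[2L])]]
    out$ratio_undefined <- r2 == 0
    out$ratio <- ifelse(out$ratio_undefined, NA_real_, r1 / r2)
  }
  out
}
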