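#' Gene-level absolute copy-number matrix
#'
#' A genes x samples matrix of absolute (ploidy-adjusted) copy numbers with
#' the gene intervals attached. Categorical 5-state and 3-level views are
#' derived on demand, never stored.
#'
#' @param acn numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns; values >= 0 or `NA`.
#' @param gene_intervals optional data.frame (`gene`, `chrom`, `start`,
#'   `end`) matching the rownames of `acn`.
#' @param rcn optional matching matrix of relative copy numbers (log2-ratio
#'   scale).
#' @return object of class `gene_cn_matrix`.
#' @export
gene_cn_matrix <- function(acn, gene_intervals = NULL, rcn = NULL) {
  stopifnot(is.matrix(acn), !is.null(rownames(acn)), !is.null(colnames(acn)))
  if (anyDuplicated(rownames(acn))) stop("gene identifiers must be unique")
  if (anyDuplicated(colnames(acn))) stop("sample identifiers must be unique")
  if (any(acn < 0, na.rm = TRUE)) stop("absolute copy numbers must be >= 0")
  if (!is.null(rcn)) stopifnot(identical(dim(rcn), dim(acn)))
  structure(list(acn = acn, gene_intervals = gene_intervals, rcn = rcn),
            class = "gene_cn_matrix")
}

#' @export
print.gene_cn_matrix <- function(x, ...) {
  cat(sprintf("<gene_cn_matrix> %d genes x %d samples\n",
              nrow(x$acn), ncol(x$acn)))
  invisible(x)
}

#' Gene-level adjusted copy number from segments
#'
#' Summarizes a region's segment-level adjusted copy numbers to one value
#' per gene: the adjusted CN of the segment with the largest overlap with
#' the gene interval; ties are broken toward the higher copy number so
#' focal amplifications are not missed.
#'
#' @param segments data.frame (`chrom`, `start`, `end`, `acn`), 0-based
#'   half-open, non-overlapping.
#' @param gene_chrom,gene_start,gene_end the gene interval.
#' @return scalar adjusted CN, or `NA` (with a warning) when the gene
#'   overlaps no segment.
#' @export
gene_acn_from_segments <- function(segments, gene_chrom, gene_start,
                                   gene_end) {
  s <- segments[segments$chrom == gene_chrom, , drop = FALSE]
  if (!nrow(s)) {
    warning("gene interval overlaps no segment (", gene_chrom, ")")
    return(NA_real_)
  }
  ov <- pmin(s$end, gene_end) - pmax(s$start, gene_start)
  keep <- ov > 0
  if (!any(keep)) {
    warning("gene interval overlaps no segment (", gene_chrom, ":",
            gene_start, "-", gene_end, ")")
    return(NA_real_)
  }
  s <- s[keep, , drop = FALSE]; ov <- ov[keep]
  best <- which(ov == max(ov))
  if (length(best) > 1L) best <- best[which.max(s$acn[best])]
  s$acn[best]
}

#' Five-state category of an adjusted copy number
#'
#' Boundaries at adjusted copy numbers 0.5, 1.5, 2.5 and 4.5, half-open on
#' the left: `[0, 0.5)` homozygous loss, `[0.5, 1.5)` heterozygous loss,
#' `[1.5, 2.5)` neutral, `[2.5, 4.5)` gain, `[4.5, Inf)` amplification.
#' Consistent with the integer definitions (gain = 3 or 4 copies,
#' amplification = 5 or more).
#'
#' @param acn numeric vector of adjusted copy numbers, >= 0 (`NA` allowed).
#' @return factor with levels `homozygous_loss`, `heterozygous_loss`,
#'   `neutral`, `gain`, `amplification`.
#' @export
categorize_acn <- function(acn) {
  if (any(acn < 0, na.rm = TRUE)) stop("adjusted copy numbers must be >= 0")
  cut(acn, breaks = c(-Inf, 0.5, 1.5, 2.5, 4.5, Inf), right = FALSE,
      labels = c("homozygous_loss", "heterozygous_loss", "neutral",
                 "gain", "amplification"))
}

#' Three-level view of an integer adjusted copy number
#'
#' Collapses integer adjusted copy numbers to the ordered levels
#' `"2"` (<= 2), `"3"` and `"4+"` (>= 4) used for trend tests across copy
#' states.
#'
#' @param acn integer vector, >= 0.
#' @return ordered factor with levels `"2" < "3" < "4+"`.
#' @export
acn_to_levels <- function(acn) {
  stopifnot(all(acn >= 0, na.rm = TRUE))
  out <- ifelse(acn <= 2, "2", ifelse(acn == 3, "3", "4+"))
  factor(out, levels = c("2", "3", "4+"), ordered = TRUE)
}

#' Cohort copy-number frequency profile
#'
#' Per-gene percentage of samples in each of the five copy-number
#' categories, over a subset of samples, plus the combined tracks
#' (amplification-or-gain and any-loss). Missing values are excluded from
#' the denominators, never imputed.
#'
#' @param matrix a [gene_cn_matrix()].
#' @param subset logical or character vector selecting samples; default all.
#' @return data.frame, one row per gene, with percentage columns and
#'   `n_samples` (non-missing count per gene).
#' @export
cohort_frequency_profile <- function(matrix, subset = NULL) {
  stopifnot(inherits(matrix, "gene_cn_matrix"))
  acn <- matrix$acn
  if (!is.null(subset)) {
    sel <- if (is.logical(subset)) which(subset) else
      match(subset, colnames(acn))
    if (!length(sel) || anyNA(sel))
      stop("empty or invalid sample subset: ",
           paste(utils::head(subset), collapse = ", "))
    acn <- acn[, sel, drop = FALSE]
  }
  if (!ncol(acn)) stop("empty sample subset")
  lv <- c("homozygous_loss", "heterozygous_loss", "neutral", "gain",
          "amplification")
  out <- t(apply(acn, 1L, function(v) {
    v <- v[!is.na(v)]
    n <- length(v)
    if (!n) return(c(rep(NA_real_, 5L), 0))
    tab <- table(factor(categorize_acn(v), levels = lv))
    c(100 * as.numeric(tab) / n, n)
  }))
  out <- as.data.frame(out)
  names(out) <- c(lv, "n_samples")
  out$amp_or_gain <- out$amplification + out$gain
  out$any_loss <- out$homozygous_loss + out$heterozygous_loss
  cbind(data.frame(gene = rownames(acn), stringsAsFactors = FALSE), out)
}

#' Frequency difference between marker-altered and marker-neutral samples
#'
#' Splits the cohort by the copy-number status of a marker gene
#' (gain-or-amplification versus the comparison group, by default neutral
#' samples only) and computes, per gene, the difference in alteration
#' frequency between the two groups: `freq(marker group) - freq(comparison
#' group)`, for amplification-or-gain and, on the reverse scale, for loss.
#' Genes are partitioned by the supplied pathway labels.
#'
#' @param matrix a [gene_cn_matrix()].
#' @param marker_gene gene id defining the grouping (e.g. `"MYC"`).
#' @param pathway_labels named character vector (gene -> pathway label,
#'   e.g. `"PI3K_RAS"` or `"other"`).
#' @param comparison `"neutral"` (default) compares against marker-neutral
#'   samples only; `"non_altered"` pools neutral and loss samples.
#' @return data.frame with `gene`, `pathway`, `diff_amp_gain`,
#'   `diff_loss` (percentage points).
#' @export
group_frequency_difference <- function(matrix, marker_gene, pathway_labels,
                                       comparison = c("neutral",
                                                      "non_altered")) {
  stopifnot(inherits(matrix, "gene_cn_matrix"))
  comparison <- match.arg(comparison)
  acn <- matrix$acn
  if (!marker_gene %in% rownames(acn))
    stop("marker gene ", marker_gene, " not present")
  mcat <- categorize_acn(acn[marker_gene, ])
  g1 <- which(mcat %in% c("gain", "amplification"))
  g2 <- if (comparison == "neutral") which(mcat == "neutral")
        else which(mcat %in% c("neutral", "heterozygous_loss",
                               "homozygous_loss"))
  if (!length(g1) || !length(g2))
    stop("marker grouping has an empty group (altered n=", length(g1),
         ", comparison n=", length(g2), ")")
  f1 <- cohort_frequency_profile(matrix, subset = colnames(acn)[g1])
  f2 <- cohort_frequency_profile(matrix, subset = colnames(acn)[g2])
  data.frame(gene = f1$gene,
             pathway = unname(pathway_labels[f1$gene]),
             diff_amp_gain = f1$amp_or_gain - f2$amp_or_gain,
             diff_loss = f1$any_loss - f2$any_loss,
             stringsAsFactors = FALSE)
}

#' Convert relative to absolute copy number
#'
#' `ACN = ploidy * 2^RCN` with RCN on the log2-ratio scale; default ploidy
#' 2 when unknown.
#'
#' @param rcn numeric, log2-ratio relative copy number.
#' @param ploidy sample ploidy.
#' @return absolute copy number.
#' @export
rcn_to_acn <- function(rcn, ploidy = 2) {
  stopifnot(all(ploidy > 0))
  ploidy * 2^rcn
}
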