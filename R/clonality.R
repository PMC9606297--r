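#' Construct an allele-specific segment profile for one tumour region
#'
#' @param patient_id,region_id identifiers.
#' @param segments data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `raw_minor`, `raw_major` (nonnegative reals).
#'   Within a chromosome segments must be sorted and non-overlapping.
#'   Rows with `raw_minor > raw_major` are swapped (convention) with a
#'   warning.
#' @param ploidy sample mean ploidy, > 0.
#' @return object of class `allelic_segment_profile`.
#' @export
allelic_segment_profile <- function(patient_id, region_id, segments, ploidy) {
  stopifnot(is.data.frame(segments),
            all(c("chrom", "start", "end", "raw_minor", "raw_major") %in%
                  names(segments)))
  if (!is.numeric(ploidy) || length(ploidy) != 1L || ploidy <= 0)
    stop("ploidy must be a single positive number")
  if (any(segments$end <= segments$start))
    stop("segments must have end > start (0-based half-open)")
  if (any(segments$raw_minor < 0) || any(segments$raw_major < 0))
    stop("raw allele copy numbers must be nonnegative")
  swp <- segments$raw_minor > segments$raw_major
  if (any(swp)) {
    warning(sum(swp), " segment(s) with raw_minor > raw_major swapped")
    tmp <- segments$raw_minor[swp]
    segments$raw_minor[swp] <- segments$raw_major[swp]
    segments$raw_major[swp] <- tmp
  }
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    if (nrow(s) > 1L && any(s$start[-1] < s$end[-nrow(s)]))
      stop("overlapping segments on ", ch, " in region ", region_id)
  }
  rownames(segments) <- NULL
  structure(list(patient_id = patient_id, region_id = region_id,
                 segments = segments, ploidy = ploidy),
            class = "allelic_segment_profile")
}

#' @export
print.allelic_segment_profile <- function(x, ...) {
  cat(sprintf("<allelic_segment_profile> %s/%s: %d segments, ploidy %.2f\n",
              x$patient_id, x$region_id, nrow(x$segments), x$ploidy))
  invisible(x)
}

#' Ploidy-normalized non-allele-specific raw copy number
#'
#' `log2((raw_minor + raw_major) / ploidy)` per segment. A segment whose
#' total raw copy number is exactly 0 is a homozygous null and maps to
#' `-Inf`, the documented sentinel, which downstream state classification
#' treats as a loss.
#'
#' @param raw_minor,raw_major nonnegative reals (vectorized).
#' @param ploidy positive real.
#' @return numeric vector of log2 ratios (`-Inf` for homozygous null).
#' @export
raw_total_cn <- function(raw_minor, raw_major, ploidy) {
  if (any(ploidy <= 0)) stop("ploidy must be positive")
  if (any(raw_minor < 0) || any(raw_major < 0))
    stop("raw copy numbers must be nonnegative")
  log2((raw_minor + raw_major) / ploidy)
}

#' Gain/loss state of a ploidy-normalized copy number value
#'
#' Gain iff `value > log2(2.5/2)`, loss iff `value < log2(1.5/2)`
#' (strict inequalities; values exactly at a threshold are neutral). The
#' homozygous-null sentinel `-Inf` classifies as loss.
#'
#' @param rtcn numeric vector of [raw_total_cn()] values.
#' @return character vector in `c("gain", "loss", "neutral")`.
#' @export
classify_state <- function(rtcn) {
  if (any(is.na(rtcn))) stop("rtcn contains NA")
  out <- rep("neutral", length(rtcn))
  out[rtcn > log2(2.5 / 2)] <- "gain"
  out[rtcn < log2(1.5 / 2)] <- "loss"
  out
}

# interval subtraction (0-based half-open) of mask from one chromosome's
# [start, end) windows, via IRanges on a 1-based closed view
subtract_mask <- function(start, end, mask_start, mask_end) {
  ir <- IRanges::IRanges(start = start + 1L, end = end)
  if (length(mask_start)) {
    mk <- IRanges::reduce(IRanges::IRanges(start = mask_start + 1L,
                                           end = mask_end))
    ir <- IRanges::setdiff(ir, mk)
  }
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Build a per-patient consensus copy-number profile
#'
#' Intersects the segmentations of all regions of one patient: consensus
#' breakpoints are the union of every region's breakpoints, masked intervals
#' are removed, and each consensus segment carries one ploidy-normalized raw
#' total copy number and one LOH flag per region (LOH iff
#' `raw_minor < loh_threshold`).
#'
#' @param profiles list of [allelic_segment_profile()]s sharing a
#'   `patient_id`.
#' @param mask optional data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open) of intervals to exclude.
#' @param loh_threshold raw minor copy number below which a segment carries
#'   loss of heterozygosity; default 0.25.
#' @return object of class `consensus_profile`: `$segments`
#'   (chrom/start/end), `$rtcn` and `$loh` matrices (segments x regions).
#' @export
build_consensus <- function(profiles, mask = NULL, loh_threshold = 0.25) {
  stopifnot(length(profiles) >= 1L)
  pid <- unique(vapply(profiles, `[[`, "", "patient_id"))
  if (length(pid) != 1L)
    stop("profiles span multiple patients: ", paste(pid, collapse = ", "))
  chrs <- lapply(profiles, function(p) sort(unique(p$segments$chrom)))
  for (i in seq_along(profiles)[-1]) {
    if (!identical(chrs[[1]], chrs[[i]]))
      stop("regions disagree on chromosome sets: ",
           profiles[[1]]$region_id, " has {",
           paste(chrs[[1]], collapse = ","), "} but ",
           profiles[[i]]$region_id, " has {",
           paste(chrs[[i]], collapse = ","), "}")
  }
  regions <- vapply(profiles, `[[`, "", "region_id")
  nseg_rows <- list(); rt_rows <- list(); loh_rows <- list()
  for (ch in chrs[[1]]) {
    bps <- sort(unique(unlist(lapply(profiles, function(p) {
      s <- p$segments[p$segments$chrom == ch, ]
      c(s$start, s$end)
    }))))
    win <- data.frame(start = bps[-length(bps)], end = bps[-1])
    mk <- if (!is.null(mask)) mask[mask$chrom == ch, , drop = FALSE]
          else data.frame(start = numeric(0), end = numeric(0))
    keep <- do.call(rbind, lapply(seq_len(nrow(win)), function(i)
      subtract_mask(win$start[i], win$end[i], mk$start, mk$end)))
    if (is.null(keep) || !nrow(keep)) next
    rt <- matrix(NA_real_, nrow(keep), length(profiles))
    lo <- matrix(NA, nrow(keep), length(profiles))
    for (j in seq_along(profiles)) {
      s <- profiles[[j]]$segments[profiles[[j]]$segments$chrom == ch, ]
      mid <- (keep$start + keep$end) / 2
      idx <- findInterval(mid, s$start)
      cov <- idx >= 1L & mid < s$end[pmax(idx, 1L)]
      rt[cov, j] <- raw_total_cn(s$raw_minor[idx[cov]], s$raw_major[idx[cov]],
                                 profiles[[j]]$ploidy)
      lo[cov, j] <- s$raw_minor[idx[cov]] < loh_threshold
    }
    nseg_rows[[ch]] <- data.frame(chrom = ch, start = keep$start,
                                  end = keep$end)
    rt_rows[[ch]] <- rt
    loh_rows[[ch]] <- lo
  }
  segments <- do.call(rbind, nseg_rows)
  rownames(segments) <- NULL
  structure(list(patient_id = pid, regions = regions, segments = segments,
                 rtcn = do.call(rbind, rt_rows),
                 loh = do.call(rbind, loh_rows),
                 loh_threshold = loh_threshold),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("<consensus_profile> %s: %d segments x %d regions\n",
              x$patient_id, nrow(x$segments), length(x$regions)))
  invisible(x)
}

#' Classify clonality of gains and losses on a consensus profile
#'
#' Per consensus segment: the gain label is `clonal` iff every region
#' classifies as gain, `subclonal` iff at least one but not all do, `none`
#' otherwise. The loss label is analogous, where a region "has loss" iff
#' its ploidy-normalized state is loss or its LOH flag is set. Gain and
#' loss labels are independent (different regions of one patient may gain
#' and lose the same locus). For single-region patients subclonality is
#' undefined: labels are restricted to `clonal`/`none` with a warning.
#'
#' @param consensus a [build_consensus()] result.
#' @return data.frame with `patient`, `chrom`, `start`, `end`,
#'   `gain_label`, `loss_label`.
#' @export
classify_clonality <- function(consensus) {
  stopifnot(inherits(consensus, "consensus_profile"))
  nr <- length(consensus$regions)
  if (nr == 1L)
    warning("single-region patient ", consensus$patient_id,
            ": subclonality undefined, labels restricted to clonal/none")
  st <- apply(consensus$rtcn, 2L, classify_state)
  if (is.null(dim(st))) st <- matrix(st, ncol = nr)
  gain <- st == "gain" & !is.na(consensus$rtcn)
  loss <- (st == "loss" | consensus$loh) & !is.na(consensus$rtcn)
  lab <- function(hits) {
    n <- rowSums(hits)
    out <- rep("none", length(n))
    out[n == nr] <- "clonal"
    out[n > 0L & n < nr] <- "subclonal"
    out
  }
  data.frame(patient = consensus$patient_id,
             chrom = consensus$segments$chrom,
             start = consensus$segments$start,
             end = consensus$segments$end,
             gain_label = lab(gain),
             loss_label = lab(loss),
             stringsAsFactors = FALSE)
}

# overlap of call segments with genomic bins, both 0-based half-open
overlap_hits <- function(calls, bins) {
  hits <- vector("list", nrow(bins))
  for (ch in unique(bins$chrom)) {
    bi <- which(bins$chrom == ch)
    ci <- which(calls$chrom == ch)
    if (!length(ci)) next
    q <- IRanges::IRanges(bins$start[bi] + 1L, bins$end[bi])
    s <- IRanges::IRanges(calls$start[ci] + 1L, calls$end[ci])
    ov <- as.data.frame(IRanges::findOverlaps(q, s))
    for (k in seq_len(nrow(ov)))
      hits[[bi[ov$queryHits[k]]]] <- c(hits[[bi[ov$queryHits[k]]]],
                                       ci[ov$subjectHits[k]])
  }
  hits
}

#' Cohort frequency track of clonal and subclonal alterations
#'
#' For genomic bins, the percentage of patients carrying a clonal gain,
#' subclonal gain, clonal loss and subclonal loss overlapping the bin, plus
#' the combined (clonal + subclonal) track per direction. A patient with
#' both clonal and subclonal segments of one direction in a bin counts as
#' clonal, so clonal\% + subclonal\% <= 100 per direction. Percentages are
#' relative to the patients with consensus coverage in the bin; bins no
#' patient covers are reported as `NA`, not 0.
#'
#' @param calls data.frame of [classify_clonality()] rows, possibly from
#'   several patients.
#' @param bins data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @return data.frame: bins plus `n_covered`, `clonal_gain`,
#'   `subclonal_gain`, `clonal_loss`, `subclonal_loss`, `total_gain`,
#'   `total_loss` (percentages).
#' @export
clonality_frequency_track <- function(calls, bins) {
  if (is.null(bins) || !nrow(bins)) stop("empty bin set")
  patients <- unique(calls$patient)
  if (!length(patients)) stop("no patients in calls")
  hits <- overlap_hits(calls, bins)
  res <- bins
  cats <- c(clonal_gain = NA, subclonal_gain = NA,
            clonal_loss = NA, subclonal_loss = NA)
  mat <- matrix(NA_real_, nrow(bins), 4L,
                dimnames = list(NULL, names(cats)))
  n_cov <- integer(nrow(bins))
  for (b in seq_len(nrow(bins))) {
    idx <- hits[[b]]
    if (is.null(idx)) next
    sub <- calls[idx, ]
    cov_pat <- unique(sub$patient)
    n_cov[b] <- length(cov_pat)
    stat <- function(label_col, lab) {
      per_pat <- vapply(cov_pat, function(p) {
        labs <- sub[[label_col]][sub$patient == p]
        if (lab == "clonal") any(labs == "clonal")
        else any(labs == "subclonal") && !any(labs == "clonal")
      }, logical(1))
      100 * sum(per_pat) / length(cov_pat)
    }
    mat[b, ] <- c(stat("gain_label", "clonal"), stat("gain_label", "subclonal"),
                  stat("loss_label", "clonal"), stat("loss_label", "subclonal"))
  }
  res$n_covered <- n_cov
  res <- cbind(res, as.data.frame(mat))
  res$total_gain <- res$clonal_gain + res$subclonal_gain
  res$total_loss <- res$clonal_loss + res$subclonal_loss
  res
}
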