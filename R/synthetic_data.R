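# Synthetic-data generators. Every generator seeds the global RNG once from
# its config and draws all samples from it in a fixed documented order, so a
# given config is bit-reproducible. Each generator returns machine-readable
# ground truth alongside the data; truth is never recomputed from the noisy
# observations.

#' Configuration for the multi-region copy-number cohort generator
#'
#' Defaults emulate a multi-region high-grade serous ovarian cancer cohort:
#' 30 patients with 2-6 sampled regions each (median 4), patient ploidies in
#' \{2, 3, 4\}, and a handful of large clonal and subclonal gains/losses per
#' patient placed on a compact six-chromosome genome.
#'
#' @param n_patients number of patients.
#' @param regions_per_patient integer range `c(lo, hi)` (or a scalar) of
#'   regions sampled per patient.
#' @param genome data.frame with `chrom` and `length` (bp).
#' @param ploidy_values,ploidy_probs per-patient base ploidy sampler.
#' @param clonal_event_rate,subclonal_event_rate expected (Poisson) numbers
#'   of planted events per patient.
#' @param event_length_mean mean (bp) of the exponential event-length
#'   distribution, truncated to the chromosome.
#' @param cn_noise_sd standard deviation of the additive Gaussian noise on
#'   each of raw minor/major copy number (truncated at 0).
#' @param mask_fraction fraction of each chromosome masked; planted events
#'   avoid masked intervals.
#' @param seed integer RNG seed.
#' @return validated list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_patients = 30L,
                              regions_per_patient = c(2L, 6L),
                              genome = data.frame(
                                chrom = paste0("chr", 1:6),
                                length = c(120e6, 100e6, 90e6, 80e6, 70e6,
                                           60e6)),
                              ploidy_values = c(2, 3, 4),
                              ploidy_probs = c(0.5, 0.3, 0.2),
                              clonal_event_rate = 6,
                              subclonal_event_rate = 6,
                              event_length_mean = 3e7,
                              cn_noise_sd = 0.1,
                              mask_fraction = 0,
                              seed = 1L) {
  if (length(regions_per_patient) == 1L)
    regions_per_patient <- rep(regions_per_patient, 2L)
  stopifnot(n_patients >= 1L, regions_per_patient[1] >= 1L,
            regions_per_patient[2] >= regions_per_patient[1],
            clonal_event_rate >= 0, subclonal_event_rate >= 0,
            event_length_mean > 0, cn_noise_sd >= 0,
            mask_fraction >= 0, mask_fraction < 1,
            length(ploidy_values) == length(ploidy_probs),
            all(ploidy_probs >= 0))
  if (!nrow(genome) || any(genome$length <= 0))
    stop("genome must be nonempty with positive chromosome lengths")
  if (subclonal_event_rate > 0 && regions_per_patient[2] < 2L)
    stop("subclonal events require >= 2 regions per patient ",
         "(a strict nonempty subset must exist)")
  structure(list(n_patients = as.integer(n_patients),
                 regions_per_patient = as.integer(regions_per_patient),
                 genome = genome, ploidy_values = ploidy_values,
                 ploidy_probs = ploidy_probs / sum(ploidy_probs),
                 clonal_event_rate = clonal_event_rate,
                 subclonal_event_rate = subclonal_event_rate,
                 event_length_mean = event_length_mean,
                 cn_noise_sd = cn_noise_sd, mask_fraction = mask_fraction,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

# allele copy numbers of a planted state, relative to patient ploidy:
# gains clear the gain threshold (total/ploidy > 1.25) and losses the loss
# threshold (total/ploidy < 0.75) with margin, so classification is exact
# at zero noise and degrades gracefully with cn_noise_sd
event_alleles <- function(ploidy, direction) {
  base_minor <- floor(ploidy / 2); base_major <- ceiling(ploidy / 2)
  if (direction == "gain") {
    c(minor = base_minor, major = base_major + ceiling(ploidy / 2))
  } else {
    c(minor = 0, major = floor(ploidy / 2))
  }
}

#' Simulate a multi-region allele-specific copy-number cohort
#'
#' Plants clonal events (present in every region of a patient) and
#' subclonal events (present in a uniformly chosen strict nonempty proper
#' subset of regions), tiles each chromosome into non-overlapping segments,
#' and adds truncated Gaussian noise to the raw allele copy numbers.
#'
#' @param config a [cohort_sim_config()].
#' @return list with `profiles` (flat list of
#'   [allelic_segment_profile()]s), `truth` (data.frame of planted events:
#'   patient, chrom, start, end, direction, clonality, regions) and `mask`
#'   (data.frame of masked intervals, possibly empty).
#' @export
simulate_multiregion_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  genome <- config$genome
  # mask: one random interval per chromosome when mask_fraction > 0
  mask <- NULL
  if (config$mask_fraction > 0) {
    mlen <- round(genome$length * config$mask_fraction)
    mstart <- floor(stats::runif(nrow(genome)) * (genome$length - mlen))
    mask <- data.frame(chrom = genome$chrom, start = mstart,
                       end = mstart + mlen)
  } else {
    mask <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0))
  }
  profiles <- list()
  truth <- list()
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%03d", p)
    n_reg <- sample(seq(config$regions_per_patient[1],
                        config$regions_per_patient[2]), 1L)
    ploidy <- sample(config$ploidy_values, 1L, prob = config$ploidy_probs)
    n_clonal <- stats::rpois(1L, config$clonal_event_rate)
    n_sub <- if (n_reg >= 2L) stats::rpois(1L, config$subclonal_event_rate)
             else 0L
    events <- plant_events(n_clonal, n_sub, n_reg, genome, mask,
                           config$event_length_mean)
    if (nrow(events)) {
      events$patient <- pid
      truth[[pid]] <- events
    }
    base <- c(minor = floor(ploidy / 2), major = ceiling(ploidy / 2))
    for (r in seq_len(n_reg)) {
      rid <- sprintf("R%02d", r)
      segs <- region_segments(events, r, genome, base, ploidy)
      if (config$cn_noise_sd > 0) {
        mi <- pmax(0, segs$raw_minor +
                     stats::rnorm(nrow(segs), 0, config$cn_noise_sd))
        ma <- pmax(0, segs$raw_major +
                     stats::rnorm(nrow(segs), 0, config$cn_noise_sd))
        segs$raw_minor <- pmin(mi, ma)
        segs$raw_major <- pmax(mi, ma)
      }
      profiles[[paste(pid, rid, sep = "_")]] <-
        allelic_segment_profile(pid, rid, segs, ploidy)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               direction = character(0), clonality = character(0),
               regions = character(0), patient = character(0))
  rownames(truth) <- NULL
  list(profiles = profiles, truth = truth, mask = mask)
}

# draw non-overlapping events avoiding the mask; subclonal events get a
# uniformly chosen strict nonempty proper subset of regions
plant_events <- function(n_clonal, n_sub, n_reg, genome, mask, len_mean) {
  n_tot <- n_clonal + n_sub
  out <- list()
  placed <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0))
  for (i in seq_len(n_tot)) {
    ok <- FALSE
    for (try in 1:25) {
      ci <- sample(nrow(genome), 1L, prob = genome$length)
      L <- min(genome$length[ci],
               max(2e6, stats::rexp(1L, 1 / len_mean)))
      st <- floor(stats::runif(1L) * (genome$length[ci] - L))
      en <- st + round(L)
      ch <- genome$chrom[ci]
      clash <- any(placed$chrom == ch & placed$start < en & placed$end > st)
      mclash <- any(mask$chrom == ch & mask$start < en & mask$end > st)
      if (!clash && !mclash) { ok <- TRUE; break }
    }
    if (!ok) next
    placed <- rbind(placed, data.frame(chrom = ch, start = st, end = en))
    clonality <- if (i <= n_clonal) "clonal" else "subclonal"
    regions <- if (clonality == "clonal") seq_len(n_reg) else {
      k <- sample(seq_len(n_reg - 1L), 1L)
      sort(sample(seq_len(n_reg), k))
    }
    out[[i]] <- data.frame(
      chrom = ch, start = st, end = en,
      direction = sample(c("gain", "loss"), 1L),
      clonality = clonality,
      regions = paste(regions, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               direction = character(0), clonality = character(0),
               regions = character(0))
}

# tile one region's genome: baseline alleles everywhere, event alleles on
# the events present in this region
region_segments <- function(events, region_idx, genome, base, ploidy) {
  rows <- list()
  for (ci in seq_len(nrow(genome))) {
    ch <- genome$chrom[ci]
    ev <- events[events$chrom == ch, , drop = FALSE]
    if (nrow(ev)) {
      pres <- vapply(strsplit(ev$regions, ","), function(r)
        region_idx %in% as.integer(r), logical(1))
      ev <- ev[pres, , drop = FALSE]
    }
    bps <- sort(unique(c(0, genome$length[ci], ev$start, ev$end)))
    seg <- data.frame(chrom = ch, start = bps[-length(bps)], end = bps[-1])
    seg$raw_minor <- base["minor"]; seg$raw_major <- base["major"]
    for (k in seq_len(nrow(ev))) {
      al <- event_alleles(ploidy, ev$direction[k])
      hit <- seg$start >= ev$start[k] & seg$end <= ev$end[k]
      seg$raw_minor[hit] <- al["minor"]
      seg$raw_major[hit] <- al["major"]
    }
    rows[[ch]] <- seg
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score recovery of planted events against clonality calls
#'
#' For every planted event, checks whether the consensus-segment calls
#' covering its footprint carry the expected direction and clonality label.
#' An event is recovered when at least `min_fraction` of its footprint
#' (length-weighted) is labelled correctly; the default 1 demands the exact
#' label over the whole footprint.
#'
#' @param calls data.frame of [classify_clonality()] rows for the cohort.
#' @param truth the `truth` table from [simulate_multiregion_cohort()].
#' @param min_fraction minimum correctly labelled footprint fraction.
#' @return `truth` with a logical `recovered` column.
#' @export
recover_planted_events <- function(calls, truth, min_fraction = 1) {
  recovered <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tv <- truth[i, ]
    sub <- calls[calls$patient == tv$patient & calls$chrom == tv$chrom &
                   calls$start < tv$end & calls$end > tv$start, ,
                 drop = FALSE]
    if (!nrow(sub)) next
    lab <- if (tv$direction == "gain") sub$gain_label else sub$loss_label
    ovl <- pmin(sub$end, tv$end) - pmax(sub$start, tv$start)
    good <- sum(ovl[lab == tv$clonality])
    recovered[i] <- good >= min_fraction * (tv$end - tv$start) - 1e-9
  }
  truth$recovered <- recovered
  truth
}

#' Configuration for the drug-plate generator
#'
#' Defaults emulate an 8-point half-log dilution series (10 nM to 10 uM on
#' a molar scale) with technical triplicates, 16 control wells, a shallow
#' five-parameter log-logistic truth curve and 5\% multiplicative noise.
#'
#' @param doses strictly increasing molar dose series (>= 4 distinct).
#' @param replicates_per_dose technical replicates per dose.
#' @param n_control_wells number of drug-free control wells.
#' @param truth_model list with `lower`, `upper`, `slope`, `inflection`
#'   (molar), `asymmetry` defining the true log-logistic curve.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param outlier_rate,outlier_magnitude per-well probability and
#'   multiplicative size of injected spikes.
#' @param signal_scale raw-signal value of a fully viable well.
#' @param seed integer RNG seed.
#' @return validated list of class `plate_sim_config`.
#' @export
plate_sim_config <- function(doses = 10^seq(-8.5, -5, by = 0.5),
                             replicates_per_dose = 3L,
                             n_control_wells = 16L,
                             truth_model = list(lower = 0.1, upper = 1,
                                                slope = 1.2,
                                                inflection = 1e-7,
                                                asymmetry = 1),
                             noise_cv = 0.05,
                             outlier_rate = 0,
                             outlier_magnitude = 5,
                             signal_scale = 1000,
                             seed = 1L) {
  if (length(unique(doses)) < 4L)
    stop("fewer than 4 distinct doses: spline fitting needs support")
  stopifnot(all(diff(doses) > 0), all(doses > 0),
            replicates_per_dose >= 1L, n_control_wells >= 1L,
            truth_model$lower <= truth_model$upper,
            noise_cv >= 0, outlier_rate >= 0, outlier_rate <= 1,
            signal_scale > 0)
  structure(list(doses = doses,
                 replicates_per_dose = as.integer(replicates_per_dose),
                 n_control_wells = as.integer(n_control_wells),
                 truth_model = truth_model, noise_cv = noise_cv,
                 outlier_rate = outlier_rate,
                 outlier_magnitude = outlier_magnitude,
                 signal_scale = signal_scale, seed = as.integer(seed)),
            class = "plate_sim_config")
}

# the true standardized response curve of a plate config, on log dose
truth_curve <- function(tm) {
  function(x) ll5_curve(x, tm$lower, tm$upper, tm$slope,
                        log(tm$inflection), tm$asymmetry)
}

#' Simulate one drug plate with analytic truth
#'
#' Control wells are drawn at the truth upper asymptote; test wells at the
#' truth curve value, both with multiplicative noise
#' `signal = mean * (1 + N(0, cv))` truncated at 0. Outlier wells are
#' injected as multiplicative spikes at the configured rate and their row
#' indices recorded. Truth AUC is the dose-range-normalized integral of the
#' truth curve over the log-dose range (adaptive quadrature); truth IC50 is
#' the exact crossing of the truth curve at 0.5, censored if absent.
#'
#' @param config a [plate_sim_config()].
#' @param sample_id,drug_id identifiers for the generated plate.
#' @return list with `plate` (a [dose_plate()]) and `truth` (list: `auc`,
#'   `ic50`, `log_ic50`, `ic50_censored`, `outlier_wells`, `model`).
#' @export
simulate_plate <- function(config, sample_id = "S1", drug_id = "D1") {
  stopifnot(inherits(config, "plate_sim_config"))
  set.seed(config$seed)
  tm <- config$truth_model
  f <- truth_curve(tm)
  ld <- log(config$doses)
  wells <- rbind(
    data.frame(dose = 0, replicate = seq_len(config$n_control_wells),
               mean = tm$upper, is_control = TRUE),
    data.frame(dose = rep(config$doses, each = config$replicates_per_dose),
               replicate = rep(seq_len(config$replicates_per_dose),
                               length(config$doses)),
               mean = rep(f(ld), each = config$replicates_per_dose),
               is_control = FALSE))
  n <- nrow(wells)
  noise <- if (config$noise_cv > 0) stats::rnorm(n, 0, config$noise_cv)
           else rep(0, n)
  signal <- pmax(0, wells$mean * config$signal_scale * (1 + noise))
  test_idx <- which(!wells$is_control)
  out_idx <- test_idx[stats::runif(length(test_idx)) < config$outlier_rate]
  signal[out_idx] <- signal[out_idx] * config$outlier_magnitude
  wells$signal <- signal
  wells$mean <- NULL
  a <- min(ld); b <- max(ld)
  truth_auc <- stats::integrate(f, a, b, rel.tol = 1e-10)$value / (b - a)
  g <- function(x) f(x) - 0.5
  censored <- g(a) * g(b) > 0
  log_ic50 <- if (censored) NA_real_ else
    stats::uniroot(g, lower = a, upper = b, tol = 1e-12)$root
  list(plate = dose_plate(wells, sample_id, drug_id),
       truth = list(auc = truth_auc, ic50 = exp(log_ic50),
                    log_ic50 = log_ic50, ic50_censored = censored,
                    outlier_wells = out_idx, model = tm))
}

#' Default cancer-gene panel for the genotype generator
#'
#' Ten PI3K/RAS-pathway genes and ten other cancer genes, with simple
#' synthetic genomic intervals.
#'
#' @return data.frame with `gene`, `pathway`, `chrom`, `start`, `end`.
#' @export
default_gene_panel <- function() {
  pi3k <- c("PIK3CA", "KRAS", "AKT1", "AKT2", "AKT3", "PTEN", "NF1",
            "GAB2", "IGF1R", "PTK6")
  other <- c("CCNE1", "TERT", "TP53", "RB1", "BRCA1", "BRCA2", "CDK12",
             "ERBB2", "CDKN2A", "MECOM")
  genes <- c(pi3k, other)
  data.frame(gene = genes,
             pathway = rep(c("PI3K_RAS", "other"), each = 10L),
             chrom = paste0("chr", (seq_along(genes) - 1L) %% 6L + 1L),
             start = (seq_along(genes)) * 1e6,
             end = (seq_along(genes)) * 1e6 + 1e5,
             stringsAsFactors = FALSE)
}

#' Configuration for the cohort genotype generator
#'
#' @param n_samples cohort size.
#' @param gene_panel data.frame with `gene` and `pathway` columns (pathway
#'   `"PI3K_RAS"` marks the co-occurring set); default [default_gene_panel()].
#' @param myc_amp_fraction fraction of samples with MYC gain/amplification.
#' @param co_occurrence_log_odds planted increase, on the log-odds scale, of
#'   the SCNA probability of PI3K/RAS genes in MYC-altered samples.
#' @param baseline_scna_rate per-gene SCNA probability in MYC-neutral
#'   samples.
#' @param seed integer RNG seed.
#' @return validated list of class `genotype_sim_config`.
#' @export
genotype_sim_config <- function(n_samples = 300L,
                                gene_panel = default_gene_panel(),
                                myc_amp_fraction = 0.4,
                                co_occurrence_log_odds = 1,
                                baseline_scna_rate = 0.15,
                                seed = 1L) {
  if (is.null(gene_panel) || !nrow(gene_panel))
    stop("empty gene panel")
  stopifnot(n_samples >= 2L, myc_amp_fraction >= 0, myc_amp_fraction <= 1,
            is.finite(co_occurrence_log_odds),
            baseline_scna_rate > 0, baseline_scna_rate < 1)
  structure(list(n_samples = as.integer(n_samples), gene_panel = gene_panel,
                 myc_amp_fraction = myc_amp_fraction,
                 co_occurrence_log_odds = co_occurrence_log_odds,
                 baseline_scna_rate = baseline_scna_rate,
                 seed = as.integer(seed)),
            class = "genotype_sim_config")
}

#' Simulate cohort genotypes with a planted MYC co-occurrence effect
#'
#' MYC-altered samples (gain or amplification) carry SCNAs in PI3K/RAS
#' genes with probability elevated by the planted log-odds; genes outside
#' the pathway are unaffected. Altered genes receive integer adjusted copy
#' numbers in the gain/amplification range; unaltered genes are diploid.
#'
#' @param config a [genotype_sim_config()].
#' @return list with `matrix` (a [gene_cn_matrix()] including the `MYC`
#'   row) and `truth` (list: `myc_altered`, `altered` gene x sample logical
#'   matrix, `co_occurrence_log_odds`).
#' @export
simulate_cohort_genotypes <- function(config) {
  stopifnot(inherits(config, "genotype_sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  panel <- config$gene_panel
  samples <- sprintf("S%03d", seq_len(n))
  myc_altered <- stats::runif(n) < config$myc_amp_fraction
  p0 <- config$baseline_scna_rate
  lo <- stats::qlogis(p0)
  acn <- matrix(2, nrow(panel) + 1L, n,
                dimnames = list(c("MYC", panel$gene), samples))
  acn["MYC", myc_altered] <- sample(3:8, sum(myc_altered), replace = TRUE)
  altered <- matrix(FALSE, nrow(panel), n,
                    dimnames = list(panel$gene, samples))
  for (g in seq_len(nrow(panel))) {
    p <- if (panel$pathway[g] == "PI3K_RAS")
      stats::plogis(lo + config$co_occurrence_log_odds * myc_altered)
    else rep(p0, n)
    hit <- stats::runif(n) < p
    altered[g, ] <- hit
    acn[panel$gene[g], hit] <- sample(c(3, 4, 5, 6), sum(hit),
                                      replace = TRUE,
                                      prob = c(0.35, 0.25, 0.25, 0.15))
  }
  iv <- rbind(data.frame(gene = "MYC", chrom = "chr8", start = 128e6,
                         end = 128.1e6),
              panel[, c("gene", "chrom", "start", "end")])
  list(matrix = gene_cn_matrix(acn, gene_intervals = iv),
       truth = list(myc_altered = myc_altered, altered = altered,
                    co_occurrence_log_odds = config$co_occurrence_log_odds))
}

#' Simulate expression, copy number and methylation with group effects
#'
#' Per gene, expression is `effect_size * CN + N(0, noise_sd)` with the
#' effect size set by the gene's group (e.g. driver/non-driver x
#' prevalent/non-prevalent); copy numbers are drawn uniformly from
#' `cn_states`. Methylation beta values are negatively coupled to the
#' CN-expression coupling: genes with stronger coupling are less
#' methylated.
#'
#' @param n_genes,n_samples dimensions.
#' @param groups character vector of group labels, one per gene (recycled
#'   if shorter).
#' @param effect_sizes named numeric vector giving the CN-expression slope
#'   per group; must cover every label in `groups`.
#' @param noise_sd expression noise standard deviation.
#' @param meth_coupling slope of the negative methylation coupling.
#' @param meth_noise_sd methylation noise on the logit scale.
#' @param cn_states integer copy-number support.
#' @param seed integer RNG seed.
#' @return list with matrices `expr`, `cn`, `meth` (genes x samples),
#'   `gene_groups` and `effect_sizes`.
#' @export
simulate_expression_cn <- function(n_genes = 200L, n_samples = 100L,
                                   groups = c("driver_prevalent",
                                              "driver_nonprevalent",
                                              "nondriver_prevalent",
                                              "nondriver_nonprevalent"),
                                   effect_sizes = c(
                                     driver_prevalent = 0.8,
                                     driver_nonprevalent = 0.3,
                                     nondriver_prevalent = 0.3,
                                     nondriver_nonprevalent = 0.1),
                                   noise_sd = 1, meth_coupling = 2,
                                   meth_noise_sd = 0.5,
                                   cn_states = 1:6, seed = 1L) {
  gene_groups <- rep_len(groups, n_genes)
  if (!all(gene_groups %in% names(effect_sizes)))
    stop("effect_sizes must name every group label: missing ",
         paste(setdiff(unique(gene_groups), names(effect_sizes)),
               collapse = ", "))
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  samples <- sprintf("S%03d", seq_len(n_samples))
  cn <- matrix(sample(cn_states, n_genes * n_samples, replace = TRUE),
               n_genes, n_samples, dimnames = list(genes, samples))
  eff <- effect_sizes[gene_groups]
  expr <- cn * eff + matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd),
                            n_genes, n_samples)
  dimnames(expr) <- dimnames(cn)
  meth <- stats::plogis(
    matrix(stats::rnorm(n_genes * n_samples, 0, meth_noise_sd),
           n_genes, n_samples) + 0.5 - meth_coupling * eff)
  dimnames(meth) <- dimnames(cn)
  list(expr = expr, cn = cn, meth = meth,
       gene_groups = stats::setNames(gene_groups, genes),
       effect_sizes = effect_sizes)
}
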