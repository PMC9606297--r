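#' Pipeline configuration
#'
#' A single configuration object binding all stages. Thresholds from the
#' analysis (LOH call, robust-weight outlier cut, ACN category boundaries,
#' IC50 level) live in one block so sensitivity sweeps are one-field
#' changes. Every random stage carries an explicit seed.
#'
#' @param out_dir output directory.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "clonality", "cnprofile", "doseresponse",
#'   "associate")`.
#' @param seeds named list of per-stage integer seeds.
#' @param cohort a [cohort_sim_config()]; built from `seeds$simulate` when
#'   `NULL`.
#' @param plates number of simulated sample x drug plates.
#' @param plate_config a [plate_sim_config()] template.
#' @param genotypes a [genotype_sim_config()]; default built from seeds.
#' @param loh_threshold,weight_cut,ic50_level threshold overrides.
#' @param bin_size genomic bin width (bp) for frequency tracks.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("scna_run_"),
                            stages = c("simulate", "clonality",
                                       "cnprofile", "doseresponse",
                                       "associate"),
                            seeds = list(simulate = 1L, doseresponse = 2L,
                                         associate = 3L),
                            cohort = NULL, plates = 6L,
                            plate_config = NULL, genotypes = NULL,
                            loh_threshold = 0.25, weight_cut = 0.4,
                            ic50_level = 0.5, bin_size = 1e7) {
  known <- c("simulate", "clonality", "cnprofile", "doseresponse",
             "associate")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known),
                                     collapse = ", "))
  for (s in c("simulate", "doseresponse", "associate"))
    if (s %in% stages && is.null(seeds[[s]]))
      stop("stage ", s, " needs an explicit seed")
  stopifnot(loh_threshold > 0, weight_cut > 0, weight_cut < 1,
            ic50_level > 0, ic50_level < 1, bin_size > 0)
  structure(list(out_dir = out_dir, stages = stages, seeds = seeds,
                 cohort = cohort, plates = as.integer(plates),
                 plate_config = plate_config, genotypes = genotypes,
                 loh_threshold = loh_threshold, weight_cut = weight_cut,
                 ic50_level = ic50_level, bin_size = bin_size),
            class = "pipeline_config")
}

config_digest <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  clean <- config
  clean$out_dir <- NULL
  jsonlite::write_json(clean, tmp, auto_unbox = TRUE, force = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes the toggled stages in order: simulate (multi-region cohort,
#' drug plates, cohort genotypes) -> clonality (consensus, calls,
#' frequency track) -> cnprofile (cohort frequency profile and marker
#' split) -> doseresponse (per-plate AUC/IC50) -> associate (co-occurrence
#' permutation test). Every run writes a manifest recording the package
#' version, a configuration digest, input checksums and per-stage seeds;
#' rerunning an identical configuration reproduces identical outputs for
#' the deterministic stages. Row counts and exclusions are logged via
#' `message()`.
#'
#' @param config a [pipeline_config()].
#' @return list of stage outputs plus `manifest`, invisibly writable under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- config$stages
  out <- list()
  manifest <- list(tool = "clonalSCNA",
                   version = as.character(utils::packageVersion("clonalSCNA")),
                   config_hash = config_digest(config),
                   seeds = config$seeds,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   input_checksums = list())

  if ("simulate" %in% st) {
    cohort_cfg <- config$cohort
    if (is.null(cohort_cfg))
      cohort_cfg <- cohort_sim_config(seed = config$seeds$simulate)
    sim <- simulate_multiregion_cohort(cohort_cfg)
    message("simulate: ", length(sim$profiles), " region profiles, ",
            nrow(sim$truth), " planted events")
    seg_path <- file.path(config$out_dir, "segments.tsv")
    write_segments(sim$profiles, seg_path)
    manifest$input_checksums$segments <- unname(tools::md5sum(seg_path))
    out$simulate <- sim
  }

  if ("clonality" %in% st) {
    if (is.null(out$simulate))
      stop("clonality stage requires the simulate stage (or its segments)",
           " to be enabled")
    sim <- out$simulate
    pids <- unique(vapply(sim$profiles, `[[`, "", "patient_id"))
    calls <- do.call(rbind, lapply(pids, function(p) {
      pr <- Filter(function(x) x$patient_id == p, sim$profiles)
      cons <- build_consensus(pr, mask = sim$mask,
                              loh_threshold = config$loh_threshold)
      classify_clonality(cons)
    }))
    message("clonality: ", nrow(calls), " consensus-segment calls across ",
            length(pids), " patients")
    genome <- if (is.null(config$cohort))
      cohort_sim_config(seed = config$seeds$simulate)$genome
    else config$cohort$genome
    bins <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
      bp <- seq(0, genome$length[i], by = config$bin_size)
      if (bp[length(bp)] < genome$length[i]) bp <- c(bp, genome$length[i])
      data.frame(chrom = genome$chrom[i], start = bp[-length(bp)],
                 end = bp[-1])
    }))
    track <- clonality_frequency_track(calls, bins)
    write_tsv_commented(calls, file.path(config$out_dir, "calls.tsv"))
    write_frequency_tracks(track, file.path(config$out_dir, "tracks"))
    out$clonality <- list(calls = calls, track = track)
  }

  if ("cnprofile" %in% st || "associate" %in% st) {
    geno_cfg <- config$genotypes
    if (is.null(geno_cfg))
      geno_cfg <- genotype_sim_config(seed = config$seeds$associate)
    geno <- simulate_cohort_genotypes(geno_cfg)
    out$genotypes <- geno
  }

  if ("cnprofile" %in% st) {
    prof <- cohort_frequency_profile(out$genotypes$matrix)
    labels <- stats::setNames(geno_cfg$gene_panel$pathway,
                              geno_cfg$gene_panel$gene)
    diffs <- group_frequency_difference(out$genotypes$matrix, "MYC",
                                        labels)
    message("cnprofile: ", nrow(prof), " genes profiled")
    utils::write.table(prof, file.path(config$out_dir,
                                       "frequency_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$cnprofile <- list(profile = prof, marker_diff = diffs)
  }

  if ("doseresponse" %in% st) {
    results <- lapply(seq_len(config$plates), function(i) {
      pc <- config$plate_config
      if (is.null(pc))
        pc <- plate_sim_config(seed = config$seeds$doseresponse + i)
      else pc$seed <- config$seeds$doseresponse + i
      sim <- simulate_plate(pc, sample_id = sprintf("S%02d", i),
                            drug_id = "D1")
      fit_dose_response(sim$plate, weight_cut = config$weight_cut,
                        ic50_level = config$ic50_level)
    })
    tab <- data.frame(
      sample = vapply(results, `[[`, "", "sample_id"),
      drug = vapply(results, `[[`, "", "drug_id"),
      auc = vapply(results, `[[`, 0, "auc"),
      ic50 = vapply(results, function(r) r$ic50 %||% NA_real_, 0),
      ic50_censored = vapply(results, `[[`, TRUE, "ic50_censored"),
      n_outliers = vapply(results, `[[`, 0L, "n_outliers"))
    message("doseresponse: ", nrow(tab), " plates fitted, ",
            sum(tab$n_outliers), " wells flagged")
    utils::write.table(tab, file.path(config$out_dir,
                                      "dose_response.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$doseresponse <- list(results = results, table = tab)
  }

  if ("associate" %in% st) {
    labels <- stats::setNames(geno_cfg$gene_panel$pathway,
                              geno_cfg$gene_panel$gene)
    test <- permutation_cooccurrence_test(
      out$genotypes$matrix, "MYC", labels, R = 2000L,
      seed = config$seeds$associate)
    message("associate: co-occurrence statistic ",
            signif(test$statistic, 3), ", p = ", signif(test$p_value, 3))
    out$associate <- test
  }

  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
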