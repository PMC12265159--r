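#' Configure an end-to-end pipeline run
#'
#' One configuration drives every stage, with each threshold defaulting to
#' its stage default: similarity 80 percent, 1000-read minimum, 5-150
#' percent fraction-sum window, calprotectin cap 2100 ug/g, 1 percent
#' human-DNA threshold, 1,000,000-read subsampling depth, alpha 0.05. The
#' configuration round-trips through YAML via [read_pipeline_config()] /
#' [write_pipeline_config()].
#'
#' @param simulate A [cohort_config()] describing the synthetic cohort to
#'   generate (the pipeline can also be fed externally loaded inputs by
#'   calling the stage functions directly).
#' @param min_similarity,min_reads,sum_bounds Methylation-profiling QC.
#' @param ddpcr_input_ng ddPCR input mass.
#' @param calprotectin_cap Clinical capping threshold.
#' @param human_threshold High-human-DNA threshold in percent.
#' @param subsample_depth Non-human read depth for the subsampling control.
#' @param alpha Significance level for the species classifier.
#' @param run_models Run the modelling stage (default TRUE).
#' @param subsample Run the subsampling control (default TRUE).
#' @param seed Integer master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = cohort_config(),
                            min_similarity = 80, min_reads = 1000L,
                            sum_bounds = c(5, 150),
                            ddpcr_input_ng = 5,
                            calprotectin_cap = 2100,
                            human_threshold = 1,
                            subsample_depth = 1e6,
                            alpha = 0.05,
                            run_models = TRUE,
                            subsample = TRUE,
                            seed = 1L) {
  structure(list(simulate = simulate, min_similarity = min_similarity,
                 min_reads = as.integer(min_reads), sum_bounds = sum_bounds,
                 ddpcr_input_ng = ddpcr_input_ng,
                 calprotectin_cap = calprotectin_cap,
                 human_threshold = human_threshold,
                 subsample_depth = subsample_depth, alpha = alpha,
                 run_models = isTRUE(run_models),
                 subsample = isTRUE(subsample), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @param config A `pipeline_config`.
#' @return `read_pipeline_config` returns a `pipeline_config`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulate %||% list()
  for (nm in c("n_per_group", "activity_probs", "richness_means"))
    if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
  if (!is.null(sim_args$human_pct_model$meanlog))
    sim_args$human_pct_model$meanlog <-
      unlist(sim_args$human_pct_model$meanlog)
  if (!is.null(sim_args$planted))
    sim_args$planted <- as.data.frame(lapply(sim_args$planted, unlist),
                                      stringsAsFactors = FALSE)
  y$simulate <- do.call(cohort_config, sim_args)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  sim <- unclass(y$simulate)
  sim$panel <- NULL
  # named vectors must be written as YAML maps to keep their names
  for (nm in c("n_per_group", "activity_probs", "richness_means"))
    sim[[nm]] <- as.list(sim[[nm]])
  sim$human_pct_model$meanlog <- as.list(sim$human_pct_model$meanlog)
  if (!is.null(sim$planted)) sim$planted <- as.list(sim$planted)
  y$simulate <- sim
  yaml::write_yaml(y, path)
  invisible(path)
}

.stage_attrition <- function(stage, n_in, n_out, excluded) {
  data.frame(stage = stage, samples_in = n_in, samples_out = n_out,
             n_excluded = length(excluded),
             excluded = paste(excluded, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Executes the seven stages in order — simulate, methylation profiling,
#' ddPCR quantification, host-read fraction, clinical harmonization and
#' inflammation metrics, microbiome ecology, and modelling — writing all
#' tables plus a machine-readable manifest (inputs, seeds, per-stage sample
#' attrition, warnings) under `out_dir`. Reruns with the same configuration
#' and seed reproduce identical tables.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out_dir, "run.log")
  notes <- list()
  note <- function(stage, type, detail) {
    msg <- sprintf("[%s] %s: %s", stage, type, detail)
    cat(msg, "\n", file = log_file, append = TRUE)
    message(msg)
    notes[[length(notes) + 1L]] <<- list(stage = stage, type = type,
                                         detail = detail)
  }
  attrition <- list()

  ## 1. simulate ---------------------------------------------------------
  sim_cfg <- config$simulate
  sim_cfg$seed <- config$seed
  cohort <- simulate_cohort(sim_cfg)
  n0 <- nrow(cohort$clinical)
  note("simulate", "info", paste("generated", n0, "samples"))
  attrition$simulate <- .stage_attrition("simulate", n0, n0, character(0))

  ## 2. methylprofile ----------------------------------------------------
  profiles <- lapply(names(cohort$reads), function(s)
    aggregate_sample(cohort$reads[[s]], cohort$panel,
                     min_similarity = config$min_similarity,
                     min_reads = config$min_reads,
                     sum_bounds = config$sum_bounds))
  names(profiles) <- names(cohort$reads)
  qc_fail <- names(profiles)[!vapply(profiles, `[[`, logical(1), "qc_pass")]
  for (s in qc_fail)
    note("methylprofile", "qc_exclusion",
         paste(s, profiles[[s]]$qc_reason, sep = ": "))
  attrition$methylprofile <- .stage_attrition(
    "methylprofile", n0, n0 - length(qc_fail), qc_fail)

  ## 3. ddpcr ------------------------------------------------------------
  quant <- quantify_ddpcr_table(cohort$droplets,
                                input_mass_ng = config$ddpcr_input_ng)
  for (s in quant$sample_id[quant$saturated])
    note("ddpcr", "saturation_flag", s)
  qmap <- setNames(quant$human_pct, quant$sample_id)
  for (s in setdiff(names(profiles), qc_fail)) {
    q <- quantify_ddpcr(droplet_counts(
      cohort$droplets$total[cohort$droplets$sample_id == s],
      cohort$droplets$positive[cohort$droplets$sample_id == s]),
      input_mass_ng = config$ddpcr_input_ng)
    profiles[[s]] <- normalize_cell_fractions(profiles[[s]], q)
  }
  attrition$ddpcr <- .stage_attrition("ddpcr", n0, n0, character(0))

  ## 4. hostfrac ---------------------------------------------------------
  rc <- cohort$read_counts
  rc$human_pct_metagenomics <- human_read_pct(rc$total_reads, rc$human_reads)
  taxprof <- tax_profile(cohort$species, rc)
  attrition$hostfrac <- .stage_attrition("hostfrac", n0, n0, character(0))

  ## 5. inflammetrics ----------------------------------------------------
  clin <- harmonize_clinical(cohort$clinical,
                             calprotectin_cap = config$calprotectin_cap)
  clin$human_reads_pct <- rc$human_pct_metagenomics[
    match(clin$sample_id, rc$sample_id)]
  clin$human_pct_source <- "metagenomics"
  ptab <- profiles_table(profiles, normalized = TRUE)
  ratio_ok <- !is.na(ptab$qc_pass) & ptab$qc_pass
  clin$nlr <- clin$ner <- NA_real_
  for (i in which(ratio_ok)) {
    s <- ptab$sample_id[i]
    j <- which(clin$sample_id == s)
    clin$nlr[j] <- nlr(profiles[[s]], normalized = TRUE)
    clin$ner[j] <- ner(profiles[[s]], normalized = TRUE)
  }
  hh <- high_human_fraction(clin[, c("group", "activity", "human_reads_pct")] |>
                              (\(d) {names(d)[3] <- "human_pct"; d})(),
                            threshold = config$human_threshold)
  attrition$inflammetrics <- .stage_attrition("inflammetrics", n0, n0,
                                              character(0))

  ## 6. ecology ----------------------------------------------------------
  div <- data.frame(sample_id = colnames(cohort$species),
                    species_count = species_count(cohort$species),
                    shannon = shannon_diversity(cohort$species),
                    stringsAsFactors = FALSE)
  ord <- rclr_pcoa(cohort$species)
  cats <- classify_species(cohort$species, clin$group, alpha = config$alpha)
  curve <- group_median_curve(cohort$species, clin$group)
  pc1 <- ord$coordinates[, 1L]
  sp_pc1 <- spearman_cor(pc1, div$species_count)
  sub_drop <- character(0)
  subsampled <- NULL
  if (config$subsample) {
    subsampled <- subsample_nonhuman(taxprof, depth = config$subsample_depth,
                                     seed = config$seed)
    sub_drop <- attr(subsampled, "dropped")
    for (s in sub_drop) note("ecology", "subsample_exclusion", s)
  }
  attrition$ecology <- .stage_attrition("ecology", n0, n0 - length(sub_drop),
                                        sub_drop)

  ## 7. models -----------------------------------------------------------
  models <- NULL
  if (config$run_models) {
    lmm <- fit_calprotectin_lmm(clin)
    spec <- classifier_spec("ControlVsIBD", "presence_absence",
                            seed = config$seed)
    feats <- build_feature_matrix(cohort$species, spec,
                                  setNames(clin$human_reads_pct,
                                           clin$sample_id))
    lab <- factor(ifelse(clin$group == "Control", "Control", "IBD"),
                  levels = c("Control", "IBD"))
    clf <- train_cv_classifier(feats, lab, spec)
    models <- list(lmm = lmm, control_vs_ibd = clf)
    note("models", "info",
         sprintf("ControlVsIBD presence-absence CV AUC = %.3f", clf$auc))
  }
  attrition$models <- .stage_attrition("models", n0, n0, character(0))

  ## ---- write outputs --------------------------------------------------
  wt <- function(df, name) write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_cohort(cohort, file.path(out_dir, "dataset"))
  wt(ptab, "profiles.tsv")
  wt(quant, "ddpcr_quant.tsv")
  wt(rc, "read_counts.tsv")
  wt(clin, "clinical_harmonized.tsv")
  wt(hh, "high_human_fraction.tsv")
  wt(div, "diversity.tsv")
  wt(data.frame(sample_id = rownames(ord$coordinates),
                ord$coordinates[, seq_len(min(5L, ncol(ord$coordinates)))]),
     "ordination.tsv")
  wt(cats, "species_categories.tsv")
  wt(curve, "median_curve.tsv")
  attr_tab <- do.call(rbind, attrition)
  wt(attr_tab, "attrition.tsv")

  manifest <- list(
    stages = names(attrition),
    seed = config$seed,
    n_samples = n0,
    thresholds = list(min_similarity = config$min_similarity,
                      min_reads = config$min_reads,
                      sum_bounds = config$sum_bounds,
                      calprotectin_cap = config$calprotectin_cap,
                      human_threshold = config$human_threshold,
                      subsample_depth = config$subsample_depth,
                      alpha = config$alpha),
    attrition = attr_tab,
    warnings = notes,
    summary = list(
      pc1_richness_spearman = sp_pc1$rho,
      pc1_richness_spearman_abs = abs(sp_pc1$rho),
      median_species_count = tapply(div$species_count, clin$group, median),
      cv_auc = if (!is.null(models)) models$control_vs_ibd$auc else NULL,
      lmm_treatment_estimate = if (!is.null(models))
        models$lmm$coefficients$estimate[
          models$lmm$coefficients$term == "treatment_advancement"] else NULL
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  invisible(list(cohort = cohort, profiles = profiles, quant = quant,
                 taxprofile = taxprof, clinical = clin,
                 high_human = hh, diversity = div, ordination = ord,
                 categories = cats, median_curve = curve,
                 subsampled = subsampled, models = models,
                 manifest = manifest))
}
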