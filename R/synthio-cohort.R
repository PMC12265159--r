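#' Configure a synthetic IBD case-control cohort
#'
#' The generator emulates the statistical structure of a pediatric
#' IBD/Control stool cohort: three study groups (Control, Crohn's disease,
#' ulcerative colitis), a longitudinal subject structure, disease-activity
#' scores on pediatric scales, fecal calprotectin driven by a linear mixed
#' model, human DNA percentage that rises with disease activity, a cell
#' mixture of the human DNA dominated by neutrophils during inflammation,
#' and a species table whose group-wise richness mirrors the roughly
#' two-fold loss of species richness in IBD (defaults: mean species count
#' about 275 in Control, 130 in CD, 170 in UC).
#'
#' @param n_per_group Named integer vector of subjects per group; defaults
#'   `c(Control = 27, CD = 40, UC = 32)`, the size of a single-center
#'   pediatric cohort.
#' @param repeat_prob Probability a subject contributes a second
#'   (longitudinal) sample; default 0.3.
#' @param samples_per_subject Optional fixed number of samples per subject;
#'   overrides `repeat_prob` when set.
#' @param activity_probs Named probability per group that a sample is in
#'   active disease; Controls have no activity score.
#' @param richness_means Named target mean species count per group.
#' @param n_species_pool Species in the simulated pool (default 400).
#' @param planted Optional data frame with columns `category`
#'   (IBD/CD/UC_LOST or _EXPANDED), `abundance_fold` and `presence_mult`,
#'   one row per planted species; see [planted_species()]. `NULL` plants
#'   nothing (all species "UNCHANGED").
#' @param human_pct_model List with `meanlog` (named: `inactive`, `active`)
#'   and `sdlog` for the log-normal human DNA percentage. Defaults put
#'   roughly a quarter of active-disease samples above 1% human DNA and very
#'   few inactive ones.
#' @param calprotectin_model Linear-model truth for fecal calprotectin
#'   (ug/g): intercept, coefficients for human reads percentage, active
#'   disease, treatment advancement and age, plus `subject_sd` (random
#'   intercept SD) and `resid_sd` (residual SD). The default treatment
#'   coefficient is -159.04 ug/g per treatment tier. The default intercept
#'   (1000) keeps the linear predictor interior to the assay range, so the
#'   stated linear structure, not boundary truncation, generates the data;
#'   values below 0 are truncated and values above the cap flagged.
#' @param total_reads_mean,total_reads_sd Metagenomic sequencing depth model
#'   (default 8e6 +- 1e6 reads/sample, the assay's target depth).
#' @param panel A `marker_panel`; default is 6 cell types x 2 markers.
#' @param methyl_depth Total targeted bisulfite reads per sample (default
#'   10,000, the assay's sequencing depth), split evenly across markers.
#' @param conversion_rate,seq_error_rate Passed to
#'   [simulate_bisulfite_reads()].
#' @param n_droplets,ddpcr_input_ng ddPCR reaction geometry (20,000 droplets
#'   on 5 ng of fecal DNA).
#' @param calprotectin_cap Assay saturation cap in ug/g (default 2100).
#' @param include_reads Generate per-sample bisulfite reads (default TRUE;
#'   disable for large cohorts where only the tabular outputs are needed).
#' @param seed Integer seed; fully determines the cohort.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = c(Control = 27L, CD = 40L, UC = 32L),
                          repeat_prob = 0.3,
                          samples_per_subject = NULL,
                          activity_probs = c(Control = 0, CD = 0.5, UC = 0.5),
                          richness_means = c(Control = 275, CD = 130, UC = 170),
                          n_species_pool = 400L,
                          planted = NULL,
                          human_pct_model = list(
                            meanlog = c(inactive = log(0.05), active = log(0.4)),
                            sdlog = 1.5),
                          calprotectin_model = list(
                            intercept = 1000, human_reads_pct = 40,
                            active = 300, treatment_advancement = -159.04,
                            age = 0, subject_sd = 100, resid_sd = 150),
                          total_reads_mean = 8e6, total_reads_sd = 1e6,
                          panel = NULL,
                          methyl_depth = 10000L,
                          conversion_rate = 0.99, seq_error_rate = 0.001,
                          n_droplets = 20000L, ddpcr_input_ng = 5,
                          calprotectin_cap = 2100,
                          include_reads = TRUE,
                          seed = 1L) {
  groups <- c("Control", "CD", "UC")
  stopifnot(all(groups %in% names(n_per_group)),
            all(groups %in% names(activity_probs)),
            all(groups %in% names(richness_means)),
            all(activity_probs >= 0 & activity_probs <= 1),
            n_species_pool >= max(richness_means))
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("category", "abundance_fold", "presence_mult") %in%
                    names(planted)))
    valid <- c("IBD_LOST", "CD_LOST", "UC_LOST",
               "IBD_EXPANDED", "CD_EXPANDED", "UC_EXPANDED", "UNCHANGED")
    if (!all(planted$category %in% valid))
      stop("unknown planted category: ",
           paste(setdiff(planted$category, valid), collapse = ", "))
  }
  structure(list(
    n_per_group = n_per_group[groups], repeat_prob = repeat_prob,
    samples_per_subject = samples_per_subject,
    activity_probs = activity_probs[groups],
    richness_means = richness_means[groups],
    n_species_pool = as.integer(n_species_pool), planted = planted,
    human_pct_model = human_pct_model,
    calprotectin_model = calprotectin_model,
    total_reads_mean = total_reads_mean, total_reads_sd = total_reads_sd,
    panel = panel, methyl_depth = as.integer(methyl_depth),
    conversion_rate = conversion_rate, seq_error_rate = seq_error_rate,
    n_droplets = as.integer(n_droplets), ddpcr_input_ng = ddpcr_input_ng,
    calprotectin_cap = calprotectin_cap,
    include_reads = isTRUE(include_reads), seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Declare planted differential species
#'
#' Convenience constructor for the `planted` slot of [cohort_config()].
#' Loss categories shrink both the presence probability and the
#' within-presence abundance in the affected group(s); expansion categories
#' raise them. IBD categories affect CD and UC jointly.
#'
#' @param category Character vector of categories.
#' @param n Number of species per listed category.
#' @param abundance_fold Within-presence abundance multiplier; defaults
#'   0.05 for loss, 20 for expansion.
#' @param presence_mult Presence-probability multiplier (capped at 1);
#'   defaults 0.2 for loss, 5 for expansion.
#' @return Data frame suitable for `cohort_config(planted = ...)`.
#' @export
planted_species <- function(category, n = 1L,
                            abundance_fold = NULL, presence_mult = NULL) {
  category <- rep(category, each = n)
  is_loss <- grepl("LOST$", category)
  if (is.null(abundance_fold))
    abundance_fold <- ifelse(is_loss, 0.05, 20)
  if (is.null(presence_mult))
    presence_mult <- ifelse(is_loss, 0.2, 5)
  data.frame(category = category,
             abundance_fold = rep_len(abundance_fold, length(category)),
             presence_mult = rep_len(presence_mult, length(category)),
             stringsAsFactors = FALSE)
}

# Which study groups a planted category perturbs.
.category_groups <- function(category) {
  switch(category,
         IBD_LOST = , IBD_EXPANDED = c("CD", "UC"),
         CD_LOST = , CD_EXPANDED = "CD",
         UC_LOST = , UC_EXPANDED = "UC",
         UNCHANGED = character(0))
}

# Dirichlet draw via gamma normalization.
.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- alpha
  g / sum(g)
}

#' Simulate a full synthetic cohort
#'
#' Generates, per sample: a clinical record (group, activity score on the
#' group's pediatric scale, fecal calprotectin from the configured linear
#' predictor plus subject random intercept and Gaussian noise, treatment
#' tier, age), the ground-truth cell mixture and human DNA percentage,
#' targeted bisulfite reads, ddPCR droplet counts, metagenomic read counts
#' (human reads binomial given the true human percentage), and a
#' species-level relative-abundance profile with planted lost/expanded taxa.
#' All ground truth is retained in the `truth` slot.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort` list with elements `config`, `panel`,
#'   `clinical`, `mixtures`, `reads`, `droplets`, `read_counts`, `species`
#'   (species x samples matrix of percent relative abundance) and `truth`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (any(config$n_per_group < 2L))
    stop("need at least 2 subjects per group")
  set.seed(config$seed)

  panel <- config$panel %||% generate_marker_panel(
    6L, 2L, seed = sample.int(.Machine$integer.max, 1L))
  cell_types <- unique(panel$cell_type)

  ## ---- subjects and samples -------------------------------------------
  groups <- rep(names(config$n_per_group), config$n_per_group)
  n_subj <- length(groups)
  subject_id <- sprintf("subj_%03d", seq_len(n_subj))
  age <- round(runif(n_subj, 6, 18))
  u_subj <- rnorm(n_subj, 0, config$calprotectin_model$subject_sd)
  n_samples_per_subj <- if (!is.null(config$samples_per_subject))
    rep(as.integer(config$samples_per_subject), n_subj) else
      1L + rbinom(n_subj, 1L, config$repeat_prob)

  samp <- data.frame(
    subject_id = rep(subject_id, n_samples_per_subj),
    group = rep(groups, n_samples_per_subj),
    age = rep(age, n_samples_per_subj),
    stringsAsFactors = FALSE
  )
  n <- nrow(samp)
  samp$sample_id <- sprintf("samp_%03d", seq_len(n))
  samp$cohort <- "SZ"

  ## ---- activity and clinical scores -----------------------------------
  p_act <- config$activity_probs[samp$group]
  active <- rbinom(n, 1L, p_act) == 1L
  samp$activity_scale <- c(Control = "none", CD = "pCDAI", UC = "pUCAI")[samp$group]
  samp$activity_score <- NA_real_
  cd <- samp$group == "CD"; uc <- samp$group == "UC"
  samp$activity_score[cd] <- ifelse(active[cd], runif(sum(cd), 10, 60),
                                    runif(sum(cd), 0, 9.9))
  samp$activity_score[uc] <- ifelse(active[uc], runif(sum(uc), 10, 85),
                                    runif(sum(uc), 0, 9.9))
  samp$activity <- ifelse(samp$group == "Control", NA_character_,
                          ifelse(active, "active", "remission"))
  samp$treatment_advancement <- ifelse(samp$group == "Control", 0L,
                                       sample(0:4, n, replace = TRUE))

  ## ---- human DNA percentage and cell mixture --------------------------
  hm <- config$human_pct_model
  state <- ifelse(!is.na(samp$activity) & samp$activity == "active",
                  "active", "inactive")
  human_pct <- pmin(100, rlnorm(n, hm$meanlog[state], hm$sdlog))

  alpha_base <- c(neutrophil = 2, monocyte = 1, B_cell = 1, T_cell = 1,
                  colon = 3, small_intestine = 2)
  alpha <- setNames(rep(1, length(cell_types)), cell_types)
  shared <- intersect(cell_types, names(alpha_base))
  alpha[shared] <- alpha_base[shared]
  mixtures <- matrix(0, n, length(cell_types),
                     dimnames = list(samp$sample_id, cell_types))
  for (i in seq_len(n)) {
    a <- alpha
    if (state[i] == "active" && "neutrophil" %in% names(a))
      a["neutrophil"] <- 8
    mixtures[i, ] <- .rdirichlet1(a)
  }

  ## ---- calprotectin from the linear-model truth -----------------------
  cm <- config$calprotectin_model
  subj_idx <- match(samp$subject_id, subject_id)
  lp <- cm$intercept +
    cm$human_reads_pct * human_pct +
    cm$active * as.numeric(state == "active") +
    cm$treatment_advancement * samp$treatment_advancement +
    cm$age * samp$age +
    u_subj[subj_idx]
  calpro_raw <- pmax(0, lp + rnorm(n, 0, cm$resid_sd))
  capped <- cap_calprotectin(calpro_raw, cap = config$calprotectin_cap)
  samp$calprotectin <- capped$value
  samp$calprotectin_capped <- capped$capped

  ## ---- metagenomic read counts ----------------------------------------
  total_reads <- pmax(1e5, round(rnorm(n, config$total_reads_mean,
                                       config$total_reads_sd)))
  human_reads <- rbinom(n, total_reads, human_pct / 100)
  read_counts <- data.frame(
    sample_id = samp$sample_id,
    total_reads = total_reads,
    human_reads = human_reads,
    nonhuman_reads = total_reads - human_reads,
    stringsAsFactors = FALSE
  )

  ## ---- species table with planted categories --------------------------
  species_ids <- sprintf("sp_%04d", seq_len(config$n_species_pool))
  q <- rbeta(config$n_species_pool, 2, 2)
  mu <- rnorm(config$n_species_pool, 0, 1.5)
  grp_names <- names(config$n_per_group)
  presence_prob <- sapply(grp_names, function(g) {
    target <- config$richness_means[[g]]
    f <- function(m) sum(pmin(1, m * q)) - target
    m <- stats::uniroot(f, c(1e-6, 1e6))$root
    pmin(1, m * q)
  })
  rownames(presence_prob) <- species_ids

  planted_categories <- setNames(rep("UNCHANGED", config$n_species_pool),
                                 species_ids)
  planted_truth <- data.frame(species = character(0), category = character(0),
                              abundance_fold = numeric(0),
                              presence_mult = numeric(0),
                              stringsAsFactors = FALSE)
  abund_fold <- matrix(1, config$n_species_pool, length(grp_names),
                       dimnames = list(species_ids, grp_names))
  pl <- config$planted
  if (!is.null(pl) && nrow(pl) > 0L) {
    pl <- pl[pl$category != "UNCHANGED", , drop = FALSE]
    # plant in prevalent species so they sit inside the analysis universe
    candidates <- species_ids[order(q, decreasing = TRUE)]
    if (nrow(pl) > length(candidates)) stop("more planted species than pool")
    chosen <- candidates[seq_len(nrow(pl))]
    for (k in seq_len(nrow(pl))) {
      sp <- chosen[k]
      affected <- .category_groups(pl$category[k])
      presence_prob[sp, affected] <-
        pmin(1, presence_prob[sp, affected] * pl$presence_mult[k])
      abund_fold[sp, affected] <- pl$abundance_fold[k]
      planted_categories[sp] <- pl$category[k]
    }
    planted_truth <- data.frame(species = chosen, category = pl$category,
                                abundance_fold = pl$abundance_fold,
                                presence_mult = pl$presence_mult,
                                stringsAsFactors = FALSE)
  }

  species <- matrix(0, config$n_species_pool, n,
                    dimnames = list(species_ids, samp$sample_id))
  for (i in seq_len(n)) {
    g <- samp$group[i]
    present <- runif(config$n_species_pool) < presence_prob[, g]
    if (!any(present)) present[which.max(presence_prob[, g])] <- TRUE
    ab <- exp(rnorm(sum(present), mu[present], 1)) *
      abund_fold[present, g]
    species[present, i] <- 100 * ab / sum(ab)
  }

  ## ---- ddPCR and bisulfite reads --------------------------------------
  ddpcr_seeds <- sample.int(1e9, n)
  read_seeds <- sample.int(1e9, n)
  true_copies <- human_pct / 100 * config$ddpcr_input_ng * 1000 / 3.3
  droplets <- data.frame(sample_id = samp$sample_id, total = NA_integer_,
                         positive = NA_integer_, negative = NA_integer_)
  for (i in seq_len(n)) {
    d <- simulate_ddpcr(true_copies[i], config$n_droplets, seed = ddpcr_seeds[i])
    droplets$total[i] <- d$total
    droplets$positive[i] <- d$positive
    droplets$negative[i] <- d$negative
  }

  reads <- NULL
  if (config$include_reads) {
    rpm <- max(1L, as.integer(round(config$methyl_depth / nrow(panel))))
    reads <- vector("list", n)
    names(reads) <- samp$sample_id
    for (i in seq_len(n)) {
      mix <- mixture_spec(mixtures[i, ], total_human_pct = human_pct[i])
      reads[[i]] <- simulate_bisulfite_reads(
        panel, mix, reads_per_marker = rpm,
        conversion_rate = config$conversion_rate,
        seq_error_rate = config$seq_error_rate,
        seed = read_seeds[i])
    }
  }

  samp <- samp[, c("sample_id", "subject_id", "cohort", "group",
                   "activity_scale", "activity_score", "activity",
                   "calprotectin", "calprotectin_capped",
                   "treatment_advancement", "age")]

  structure(list(
    config = config, panel = panel, clinical = samp,
    mixtures = mixtures, reads = reads, droplets = droplets,
    read_counts = read_counts, species = species,
    truth = list(
      mixtures = mixtures, human_pct = setNames(human_pct, samp$sample_id),
      true_copies = setNames(true_copies, samp$sample_id),
      calprotectin_model = cm,
      subject_intercepts = setNames(u_subj, subject_id),
      active = setNames(state == "active", samp$sample_id),
      planted = planted_truth,
      planted_categories = planted_categories,
      presence_prob = presence_prob
    )
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic fecal DNA cohort\n")
  tab <- table(x$clinical$group)
  cat("  samples:", nrow(x$clinical), "(",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  cat("  species pool:", nrow(x$species),
      "| markers:", nrow(x$panel),
      "| reads:", if (is.null(x$reads)) "not generated" else "per sample", "\n")
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Emits the pipeline's on-disk input formats: marker panel TSV, one FASTQ
#' per sample (gzipped), droplet-count TSV, read-count TSV, a
#' MetaPhlAn-style merged species table (rows `k__Bacteria|s__<species>`,
#' values percent relative abundance), the clinical table, and a JSON
#' ground-truth bundle.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_marker_panel(cohort$panel, file.path(dir, "panel.tsv"))
  write.table(cohort$droplets, file.path(dir, "droplets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$read_counts, file.path(dir, "read_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sp <- data.frame(clade_name = paste0("k__Bacteria|s__", rownames(cohort$species)),
                   cohort$species, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(sp, file.path(dir, "species_profile.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$reads)) {
    fdir <- file.path(dir, "fastq")
    dir.create(fdir, showWarnings = FALSE)
    for (s in names(cohort$reads))
      write_reads_fastq(cohort$reads[[s]],
                        file.path(fdir, paste0(s, ".fastq.gz")))
  }
  truth <- cohort$truth
  truth$mixtures <- as.data.frame(truth$mixtures)
  truth$presence_prob <- as.data.frame(truth$presence_prob)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
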