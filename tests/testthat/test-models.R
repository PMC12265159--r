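# Shared minimal classification fixture: labels driven by species presence.
clf_fixture <- function(seed = 1, n = 120, n_sp = 60, keep = 0.15) {
  set.seed(seed)
  lab <- factor(rep(c("Control", "IBD"), length.out = n))
  m <- matrix(rlnorm(n_sp * n), n_sp, n,
              dimnames = list(paste0("sp", 1:n_sp), paste0("s", 1:n)))
  # IBD samples lose a block of species
  m[1:20, lab == "IBD"] <- m[1:20, lab == "IBD"] *
    rbinom(sum(lab == "IBD") * 20, 1, keep)
  m <- apply(m, 2, function(x) 100 * x / sum(x))
  list(species = m, labels = lab)
}

test_that("noiseless mixed-model data is explained almost perfectly", {
  co <- simulate_cohort(cohort_config(
    n_per_group = c(Control = 20, CD = 20, UC = 20),
    samples_per_subject = 3,
    calprotectin_model = list(intercept = 1500, human_reads_pct = 40,
                              active = 300, treatment_advancement = -159.04,
                              age = 0, subject_sd = 50, resid_sd = 0),
    human_pct_model = list(meanlog = c(inactive = log(0.1),
                                       active = log(0.5)), sdlog = 0.3),
    include_reads = FALSE, seed = 21))
  clin <- harmonize_clinical(co$clinical)
  clin$human_reads_pct <- co$truth$human_pct[clin$sample_id]
  # a zero-residual fit is numerically degenerate for REML; convergence
  # chatter is expected and irrelevant to the recovered coefficients
  fit <- suppressWarnings(suppressMessages(fit_calprotectin_lmm(clin)))
  expect_gte(fit$r2_conditional, 0.999)
  est <- fit$coefficients
  expect_equal(est$estimate[est$term == "treatment_advancement"], -159.04,
               tolerance = 1e-3)
})

test_that("null predictors give near-zero marginal R2", {
  set.seed(3)
  n <- 400
  d <- data.frame(calprotectin = rnorm(n, 500, 200),
                  human_reads_pct = rlnorm(n), active = rbinom(n, 1, 0.5),
                  treatment_advancement = sample(0:4, n, TRUE),
                  age = runif(n, 6, 18),
                  subject_id = rep(sprintf("p%03d", 1:100), each = 4))
  d$calprotectin <- pmax(0, d$calprotectin)
  fit <- suppressMessages(fit_calprotectin_lmm(d))
  expect_lte(fit$r2_marginal, 0.05)
})

test_that("capped records are excluded and singular grouping falls back", {
  set.seed(4)
  n <- 60
  d <- data.frame(calprotectin = runif(n, 0, 3000),
                  human_reads_pct = rlnorm(n), active = rbinom(n, 1, 0.5),
                  treatment_advancement = sample(0:4, n, TRUE),
                  age = runif(n, 6, 18),
                  subject_id = sprintf("p%03d", 1:n))  # one sample each
  cc <- cap_calprotectin(d$calprotectin)
  d$calprotectin <- cc$value; d$calprotectin_capped <- cc$capped
  expect_warning(fit <- fit_calprotectin_lmm(d), "one observation per level")
  expect_true(fit$fallback_lm)
  expect_equal(fit$n, sum(!d$calprotectin_capped))
  expect_equal(fit$n_excluded_capped, sum(d$calprotectin_capped))
})

test_that("a perfectly separating feature yields AUC 1", {
  set.seed(5)
  n <- 60
  x <- cbind(signal = rep(c(0, 1), each = n / 2),
             noise = rnorm(n))
  rownames(x) <- paste0("s", 1:n)
  lab <- factor(rep(c("a", "b"), each = n / 2))
  spec <- classifier_spec(nrounds = 30, seed = 2)
  fit <- train_cv_classifier(x, lab, spec)
  expect_equal(fit$auc, 1)
  # out-of-fold predictions cover every sample exactly once
  expect_setequal(fit$oof$sample_id, rownames(x))
  expect_equal(anyDuplicated(fit$oof$sample_id), 0)
})

test_that("CV AUC is invariant to sample order", {
  fx <- clf_fixture(seed = 6)
  spec <- classifier_spec(feature_blocks = c("species", "species_count"),
                          nrounds = 40, seed = 3)
  feats <- build_feature_matrix(fx$species, spec)
  fit1 <- train_cv_classifier(feats, fx$labels, spec)
  perm <- sample(nrow(feats))
  fit2 <- train_cv_classifier(feats[perm, ], fx$labels[perm], spec)
  expect_equal(fit1$auc, fit2$auc, tolerance = 1e-12)
})

test_that("presence/absence and abundance representations agree on presence signal", {
  fx <- clf_fixture(seed = 7)
  hr <- setNames(rep(0.5, ncol(fx$species)), colnames(fx$species))
  spec_pa <- classifier_spec(representation = "presence_absence",
                             nrounds = 60, seed = 4)
  spec_ra <- classifier_spec(representation = "relative_abundance",
                             nrounds = 60, seed = 4)
  f_pa <- build_feature_matrix(fx$species, spec_pa, hr)
  f_ra <- build_feature_matrix(fx$species, spec_ra, hr)
  expect_true(all(f_pa[, grepl("^sp[0-9]", colnames(f_pa))] %in% c(0, 1)))
  auc_pa <- train_cv_classifier(f_pa, fx$labels, spec_pa)$auc
  auc_ra <- train_cv_classifier(f_ra, fx$labels, spec_ra)$auc
  expect_lt(abs(auc_pa - auc_ra), 0.1)
})

test_that("external validation reconciles features and bounds behave", {
  fx <- clf_fixture(seed = 8, keep = 0.5)
  spec <- classifier_spec(feature_blocks = "species", nrounds = 150, seed = 5)
  feats <- build_feature_matrix(fx$species, spec)
  fit <- train_cv_classifier(feats, fx$labels, spec)
  # validating on the training cohort itself: optimistic upper bound
  val_self <- external_validate(fit, feats, fx$labels)
  expect_gte(val_self$auc + 1e-9, fit$auc)
  expect_equal(val_self$reconciliation$n_imputed, 0)
  # held-out cohort from the same generator stays close to the CV AUC
  fx2 <- clf_fixture(seed = 88, keep = 0.5)
  feats2 <- build_feature_matrix(fx2$species, spec)
  val <- external_validate(fit, feats2, fx2$labels)
  expect_lt(abs(val$auc - fit$auc), 0.1)
  # missing species are imputed absent; low overlap warns but runs
  feats3 <- feats2[, 1:10]
  expect_warning(val3 <- external_validate(fit, feats3, fx2$labels),
                 "overlap")
  expect_equal(val3$reconciliation$n_imputed, ncol(feats) - 10)
})

test_that("feature importance ranks the informative feature and SHAP adds up", {
  set.seed(9)
  n <- 80
  x <- cbind(signal = rep(c(0, 1), each = n / 2),
             constant = rep(1, n),
             noise = rnorm(n))
  rownames(x) <- paste0("s", 1:n)
  lab <- factor(rep(c("a", "b"), each = n / 2))
  fit <- train_cv_classifier(x, lab, classifier_spec(nrounds = 30, seed = 6))
  fi <- feature_importance(fit, x)
  expect_equal(fi$importance$Feature[1], "signal")
  expect_false("constant" %in% fi$importance$Feature)  # zero gain: unused
  expect_equal(colnames(fi$shap), colnames(x))
  expect_true(all(abs(fi$shap[, "constant"]) == 0))
  # Shapley additivity: per-sample contributions + base = margin
  d <- xgboost::xgb.DMatrix(x, nthread = 1)
  margin <- predict(fit$model, d, outputmargin = TRUE)
  recon <- rowSums(fi$shap) + fi$base_value
  expect_lt(max(abs(recon - margin)), 1e-6)
})

test_that("adding the human-reads block never lowers training AUC", {
  fx <- clf_fixture(seed = 10)
  hr <- setNames(ifelse(fx$labels == "IBD", rlnorm(1, 0), rlnorm(1, -2)),
                 colnames(fx$species))
  spec1 <- classifier_spec(feature_blocks = "species", nrounds = 40, seed = 7)
  spec2 <- classifier_spec(feature_blocks = c("species", "human_reads_pct"),
                           nrounds = 40, seed = 7)
  f1 <- build_feature_matrix(fx$species, spec1)
  f2 <- build_feature_matrix(fx$species, spec2, hr)
  fit1 <- train_cv_classifier(f1, fx$labels, spec1)
  fit2 <- train_cv_classifier(f2, fx$labels, spec2)
  auc_train <- function(fit, f) {
    p <- predict(fit$model, xgboost::xgb.DMatrix(f, nthread = 1))
    as.numeric(pROC::auc(pROC::roc(as.integer(fx$labels) - 1, p,
                                   quiet = TRUE)))
  }
  expect_gte(auc_train(fit2, f2) + 1e-9, auc_train(fit1, f1))
})

test_that("degenerate classifier inputs error cleanly", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), NULL))
  expect_error(train_cv_classifier(x, factor(rep("a", 10))), "2 classes")
  expect_error(train_cv_classifier(x, factor(rep(c("a", "b"), c(9, 1))),
                                   classifier_spec(n_folds = 5)),
               "stratification")
})
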