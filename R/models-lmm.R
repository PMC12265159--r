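#' Mixed-effects regression of fecal calprotectin
#'
#' Fits, by REML, a linear mixed model of the form
#' `calprotectin ~ fixed terms + (1 | random factor) [+ ...]` — e.g.
#' human reads percentage + disease activity + treatment advancement + age
#' with a per-subject random intercept for longitudinal cohorts, or the
#' neutrophil variant with random intercepts for subject and integer-year
#' age. Records flagged as capped at assay saturation are excluded (their
#' stored value is artificial). When a random factor has as many levels as
#' there are observations (no replication), the grouping is uninformative
#' and the function falls back to a fixed-effects-only `lm()` fit with a
#' warning.
#'
#' Both Nakagawa R-squareds are reported: marginal (fixed effects only) and
#' conditional (fixed plus random), computed as variance of the
#' fixed-effect linear predictor, plus summed random-intercept variances
#' for the conditional version, over the total including residual variance.
#'
#' @param data Data frame holding every model term.
#' @param response Response column (default `"calprotectin"`).
#' @param fixed_terms Character vector of fixed-effect columns.
#' @param random Character vector of random-intercept grouping columns
#'   (default `"subject_id"`).
#' @param capped_col Logical column flagging capped responses to exclude;
#'   `NULL` to skip exclusion (default `"calprotectin_capped"` when
#'   present).
#' @return A `calprotectin_lmm`: list with `coefficients` (estimate, SE,
#'   df, t, p per fixed term), `r2_marginal`, `r2_conditional`,
#'   `varcomp`, `n`, `n_excluded_capped`, `fallback_lm`, and the fitted
#'   model in `fit`.
#' @export
fit_calprotectin_lmm <- function(data, response = "calprotectin",
                                 fixed_terms = c("human_reads_pct",
                                                 "active",
                                                 "treatment_advancement",
                                                 "age"),
                                 random = "subject_id",
                                 capped_col = if ("calprotectin_capped" %in%
                                                  names(data))
                                   "calprotectin_capped" else NULL) {
  stopifnot(response %in% names(data), all(fixed_terms %in% names(data)),
            all(random %in% names(data)))
  n_excl <- 0L
  if (!is.null(capped_col)) {
    stopifnot(capped_col %in% names(data))
    n_excl <- sum(data[[capped_col]], na.rm = TRUE)
    data <- data[!data[[capped_col]], , drop = FALSE]
  }
  keep <- complete.cases(data[, c(response, fixed_terms, random)])
  data <- data[keep, , drop = FALSE]
  n <- nrow(data)

  informative <- vapply(random, function(r)
    length(unique(data[[r]])) < n, logical(1))
  fallback <- !any(informative)
  if (fallback && length(random) > 0L)
    warning("random grouping(s) have one observation per level; ",
            "falling back to fixed-effects-only fit")

  fixed_rhs <- paste(fixed_terms, collapse = " + ")
  if (!fallback) {
    ran_rhs <- paste(sprintf("(1 | %s)", random[informative]),
                     collapse = " + ")
    form <- as.formula(paste(response, "~", fixed_rhs, "+", ran_rhs))
    fit <- lmerTest::lmer(form, data = data, REML = TRUE)
    sm <- coef(summary(fit))
    coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                        se = sm[, "Std. Error"], df = sm[, "df"],
                        t = sm[, "t value"], p = sm[, "Pr(>|t|)"],
                        row.names = NULL, stringsAsFactors = FALSE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_ran <- sum(vc$vcov[is.na(vc$var2) & vc$grp != "Residual"])
    var_res <- vc$vcov[vc$grp == "Residual"]
    pred_fixed <- as.vector(lme4::getME(fit, "X") %*% lme4::fixef(fit))
  } else {
    form <- as.formula(paste(response, "~", fixed_rhs))
    fit <- lm(form, data = data)
    sm <- coef(summary(fit))
    coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                        se = sm[, "Std. Error"], df = fit$df.residual,
                        t = sm[, "t value"], p = sm[, "Pr(>|t|)"],
                        row.names = NULL, stringsAsFactors = FALSE)
    var_ran <- 0
    var_res <- summary(fit)$sigma^2
    pred_fixed <- fitted(fit)
    vc <- data.frame(grp = "Residual", vcov = var_res)
  }
  var_fix <- var(pred_fixed)
  denom <- var_fix + var_ran + var_res
  structure(list(
    fit = fit, coefficients = coefs,
    r2_marginal = var_fix / denom,
    r2_conditional = (var_fix + var_ran) / denom,
    varcomp = vc, n = n, n_excluded_capped = n_excl,
    fallback_lm = fallback
  ), class = "calprotectin_lmm")
}

#' @export
print.calprotectin_lmm <- function(x, ...) {
  cat("Calprotectin mixed model (n =", x$n, ";", x$n_excluded_capped,
      "capped records excluded",
      if (x$fallback_lm) "; fixed-effects fallback" else "", ")\n")
  print(transform(x$coefficients,
                  estimate = signif(estimate, 5), se = signif(se, 4),
                  df = round(df, 1), t = round(t, 2), p = signif(p, 3)),
        row.names = FALSE)
  cat(sprintf("R2 marginal = %.3f, conditional = %.3f\n",
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}
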