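#' Default activity-score conversion tables
#'
#' Threshold tables mapping numeric disease-activity scores to the levels
#' remission / mild / moderate / severe. Cut points follow the standard
#' clinical conversions: pUCAI < 10 remission, 10-34 mild, 35-64 moderate,
#' >= 65 severe; pCDAI < 10 remission, 10-30 mild, > 30 moderate; HBI <= 4
#' remission, 5-7 mild, 8-16 moderate, > 16 severe; SCCAI <= 2 remission,
#' 3-5 mild, 6-11 moderate, > 11 severe. Each entry has `cuts` (level
#' boundaries), `open` (TRUE: level starts strictly above the cut) and
#' `labels`. All tables are overridable.
#'
#' @return Named list of scale tables.
#' @export
activity_tables <- function() {
  list(
    pUCAI = list(cuts = c(10, 35, 65), open = c(FALSE, FALSE, FALSE),
                 labels = c("remission", "mild", "moderate", "severe")),
    pCDAI = list(cuts = c(10, 30), open = c(FALSE, TRUE),
                 labels = c("remission", "mild", "moderate")),
    HBI = list(cuts = c(4, 7, 16), open = c(TRUE, TRUE, TRUE),
               labels = c("remission", "mild", "moderate", "severe")),
    SCCAI = list(cuts = c(2, 5, 11), open = c(TRUE, TRUE, TRUE),
                 labels = c("remission", "mild", "moderate", "severe"))
  )
}

#' Harmonize a disease-activity score to remission/active
#'
#' Maps a numeric score on its scale to the standard four severity levels,
#' then collapses every level other than remission into `active` so that
#' pediatric (pUCAI, pCDAI) and adult (HBI, SCCAI) scales are comparable.
#' Scale `"none"` (e.g. Controls) yields `NA` for both.
#'
#' @param score Numeric score(s).
#' @param scale Scale name(s): one of the configured tables or `"none"`;
#'   recycled against `score`.
#' @param tables Threshold tables, see [activity_tables()].
#' @return Data frame with columns `level` (remission/mild/moderate/severe)
#'   and `activity` (remission/active).
#' @export
harmonize_activity <- function(score, scale, tables = activity_tables()) {
  n <- max(length(score), length(scale))
  score <- rep_len(score, n); scale <- rep_len(as.character(scale), n)
  unknown <- setdiff(unique(scale), c(names(tables), "none"))
  if (length(unknown) > 0L)
    stop("unknown activity scale: ", paste(unknown, collapse = ", "))
  level <- rep(NA_character_, n)
  for (sc in setdiff(unique(scale), "none")) {
    tb <- tables[[sc]]
    i <- which(scale == sc & !is.na(score))
    if (length(i) == 0L) next
    idx <- vapply(score[i], function(s)
      sum(ifelse(tb$open, s > tb$cuts, s >= tb$cuts)), numeric(1))
    level[i] <- tb$labels[idx + 1L]
  }
  activity <- ifelse(is.na(level), NA_character_,
                     ifelse(level == "remission", "remission", "active"))
  data.frame(level = level, activity = activity, stringsAsFactors = FALSE)
}

#' Cap fecal calprotectin at assay saturation
#'
#' The calprotectin assay saturates; values above the cap (default
#' 2100 ug/g) are stored at the cap and flagged. Flagged records must be
#' excluded from calprotectin regressions (the stored value is artificial).
#' A value exactly at the cap is not flagged (strict inequality).
#'
#' @param value Numeric calprotectin value(s), ug/g, >= 0.
#' @param cap Saturation cap (default 2100).
#' @return List with `value` (capped) and `capped` (logical flag).
#' @export
cap_calprotectin <- function(value, cap = 2100) {
  if (any(value < 0, na.rm = TRUE)) stop("calprotectin must be >= 0")
  list(value = pmin(value, cap), capped = !is.na(value) & value > cap)
}

#' Default treatment-tier vocabulary
#'
#' Treatment advancement encodes the therapy escalation ladder as an
#' ordinal 0-4: 0 none; 1 ASA (oral or rectal), antibiotics or dietary
#' supplement; 2 steroids; 3 immunomodulators; 4 immunosuppressants or
#' biologics. Synonyms can be added by extending the returned map.
#'
#' @return Named integer vector mapping (lower-case) treatment names to
#'   tiers.
#' @export
treatment_tiers <- function() {
  c("none" = 0L,
    "asa" = 1L, "asa (oral and rectal)" = 1L, "5-asa" = 1L,
    "mesalamine" = 1L, "antibiotics" = 1L, "dietary supplement" = 1L,
    "steroids" = 2L, "corticosteroids" = 2L,
    "immunomodulators" = 3L,
    "immunosuppressants" = 4L, "biologics" = 4L)
}

#' Treatment advancement of a treatment list
#'
#' A patient on several concurrent therapies is scored at the maximum tier
#' among them ("advancement" semantics).
#'
#' @param treatments Character vector of treatment names for one patient.
#' @param vocab Name-to-tier map, see [treatment_tiers()].
#' @return Integer tier 0-4.
#' @export
treatment_advancement <- function(treatments, vocab = treatment_tiers()) {
  stopifnot(length(treatments) >= 1L)
  key <- tolower(trimws(treatments))
  unknown <- treatments[!(key %in% names(vocab))]
  if (length(unknown) > 0L)
    stop("unknown treatment name(s): ", paste(unique(unknown), collapse = ", "))
  max(vocab[key])
}

# Pull named cell-type fractions from a profile or a named vector;
# errors listing any missing cell type.
.cell_fractions <- function(x, needed, normalized = FALSE) {
  fr <- if (inherits(x, "sample_methylation_profile")) {
    if (normalized) {
      if (is.null(x$normalized_fraction))
        stop("profile has no normalized fractions; supply ddPCR human %")
      x$normalized_fraction
    } else x$per_cell_type_fraction
  } else x
  missing <- setdiff(needed, names(fr))
  if (length(missing) > 0L)
    stop("missing cell type(s): ", paste(missing, collapse = ", "))
  fr[needed]
}

#' Neutrophil-to-lymphocyte DNA ratio (NLR)
#'
#' Ratio of the neutrophil DNA percentage to the lymphocyte (B plus T cell)
#' DNA percentage. Numerator and denominator must come from the same
#' normalization level (both raw fractions of human DNA, or both
#' ddPCR-normalized fractions of fecal DNA). The denominator receives a
#' small pseudocount `epsilon` (default 0.01 percentage points) so the
#' ratio stays finite when lymphocyte DNA is undetected; with
#' `epsilon = 0` a zero denominator under a nonzero numerator is an error.
#'
#' @param x A `sample_methylation_profile` or a named numeric vector of
#'   cell-type percentages.
#' @param epsilon Denominator pseudocount in percentage points.
#' @param normalized Use ddPCR-normalized fractions (default FALSE).
#' @return The ratio (0 when the neutrophil percentage is 0).
#' @export
nlr <- function(x, epsilon = 0.01, normalized = FALSE) {
  fr <- .cell_fractions(x, c("neutrophil", "B_cell", "T_cell"), normalized)
  .ratio(fr[["neutrophil"]], fr[["B_cell"]] + fr[["T_cell"]], epsilon)
}

#' Neutrophil-to-epithelial DNA ratio (NER)
#'
#' As [nlr()], with the denominator the epithelial (small intestine plus
#' colon) DNA percentage.
#'
#' @inheritParams nlr
#' @return The ratio.
#' @export
ner <- function(x, epsilon = 0.01, normalized = FALSE) {
  fr <- .cell_fractions(x, c("neutrophil", "small_intestine", "colon"),
                        normalized)
  .ratio(fr[["neutrophil"]], fr[["small_intestine"]] + fr[["colon"]], epsilon)
}

.ratio <- function(num, denom, epsilon) {
  if (num == 0) return(0)
  if (denom + epsilon == 0)
    stop("zero denominator with epsilon = 0; set epsilon > 0 to use a ",
         "pseudocount")
  num / (denom + epsilon)
}

#' Fraction of samples with high human DNA, per group and activity
#'
#' Per (group x activity) cell, the fraction of samples whose human DNA
#' percentage strictly exceeds the threshold (default 1 percent — "over
#' 1%" is strict).
#'
#' @param data Data frame with columns `group`, `activity` and `human_pct`.
#' @param threshold Percent threshold (default 1).
#' @return Data frame `group`, `activity`, `n`, `n_above`, `fraction`;
#'   empty cells yield `NA` with a warning.
#' @export
high_human_fraction <- function(data, threshold = 1) {
  stopifnot(all(c("group", "activity", "human_pct") %in% names(data)))
  act <- ifelse(is.na(data$activity), "none", as.character(data$activity))
  cells <- unique(data.frame(group = data$group, activity = act,
                             stringsAsFactors = FALSE))
  cells <- cells[order(cells$group, cells$activity), ]
  res <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- data$group == cells$group[i] & act == cells$activity[i]
    n <- sum(sel)
    n_above <- sum(data$human_pct[sel] > threshold, na.rm = TRUE)
    data.frame(group = cells$group[i], activity = cells$activity[i],
               n = n, n_above = n_above,
               fraction = if (n == 0L) NA_real_ else n_above / n,
               stringsAsFactors = FALSE)
  }))
  if (any(res$n == 0L)) warning("empty group x activity cell(s)")
  rownames(res) <- NULL
  res
}

#' Harmonize a raw clinical table
#'
#' Applies the harmonization steps in one pass: activity level from score
#' and scale, calprotectin capping with flag, and optional relabelling of
#' IBD-unclassified records as UC.
#'
#' @param clinical Data frame with at least `activity_scale`,
#'   `activity_score`, `calprotectin` and `group`.
#' @param calprotectin_cap Cap in ug/g (default 2100).
#' @param ibdu_as_uc Relabel group "IBDU" as "UC" (default TRUE).
#' @param tables Activity threshold tables.
#' @return The table with `activity_level`, `activity`, `calprotectin`
#'   (capped) and `calprotectin_capped` columns set.
#' @export
harmonize_clinical <- function(clinical, calprotectin_cap = 2100,
                               ibdu_as_uc = TRUE,
                               tables = activity_tables()) {
  stopifnot(all(c("activity_scale", "activity_score", "calprotectin",
                  "group") %in% names(clinical)))
  if (ibdu_as_uc) clinical$group[clinical$group == "IBDU"] <- "UC"
  ha <- harmonize_activity(clinical$activity_score, clinical$activity_scale,
                           tables)
  clinical$activity_level <- ha$level
  clinical$activity <- ha$activity
  cc <- cap_calprotectin(clinical$calprotectin, calprotectin_cap)
  clinical$calprotectin <- cc$value
  clinical$calprotectin_capped <- cc$capped
  # numeric active-disease indicator for regression models; subjects with
  # no activity score (Controls) sit at the inactive baseline
  clinical$active <- as.integer(!is.na(clinical$activity) &
                                  clinical$activity == "active")
  clinical
}
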