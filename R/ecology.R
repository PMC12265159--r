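#' Species count (richness) of a sample
#'
#' Number of species with relative abundance strictly greater than zero.
#'
#' @param x Numeric vector of abundances, or a species x samples matrix
#'   (returns a per-sample named vector), or a `tax_profile`.
#' @return Integer count(s).
#' @export
species_count <- function(x) {
  if (inherits(x, "tax_profile")) x <- x$matrix
  if (is.matrix(x)) {
    if (any(x < 0)) stop("abundances must be >= 0")
    return(colSums(x > 0))
  }
  if (any(x < 0)) stop("abundances must be >= 0")
  sum(x > 0)
}

#' Shannon diversity (natural log)
#'
#' `H = -sum p_i ln p_i` over the nonzero proportions after renormalizing
#' the abundance vector. Delegates to [vegan::diversity()].
#'
#' @param x Numeric abundance vector, or a species x samples matrix
#'   (per-sample result), or a `tax_profile`.
#' @return Shannon index in nats.
#' @export
shannon_diversity <- function(x) {
  if (inherits(x, "tax_profile")) x <- x$matrix
  if (is.matrix(x)) {
    if (any(colSums(x) == 0)) stop("all-zero sample in matrix")
    return(vegan::diversity(t(x), index = "shannon"))
  }
  if (any(x < 0)) stop("abundances must be >= 0")
  if (sum(x) == 0) stop("all-zero abundance vector")
  vegan::diversity(x, index = "shannon")
}

#' Robust centered log-ratio transform
#'
#' Per sample, nonzero abundances are transformed to
#' `ln(x / geometric mean of the sample's nonzero values)`; zeros stay 0
#' (the robust-clr, "robust Aitchison" convention: matched zeros contribute
#' nothing to distances). The transformed nonzero entries of each sample
#' sum to 0.
#'
#' @param mat Species x samples matrix (or `tax_profile`) of non-negative
#'   abundances.
#' @return Matrix of the same shape.
#' @export
rclr_transform <- function(mat) {
  if (inherits(mat, "tax_profile")) mat <- mat$matrix
  stopifnot(is.matrix(mat), all(mat >= 0))
  out <- mat
  for (i in seq_len(ncol(mat))) {
    nz <- mat[, i] > 0
    if (!any(nz)) {
      nm <- colnames(mat)[i] %||% as.character(i)
      stop("sample '", nm, "' has no nonzero abundances")
    }
    gm <- exp(mean(log(mat[nz, i])))
    out[nz, i] <- log(mat[nz, i] / gm)
    out[!nz, i] <- 0
  }
  out
}

#' Principal coordinates on the robust Aitchison geometry
#'
#' PCoA with the robust Aitchison distance is equivalent to principal
#' components of the rclr-transformed, column-centered data: Euclidean
#' distances between the returned coordinate rows (over all components)
#' equal the robust Aitchison distances between samples. Run on unfiltered
#' relative abundances to respect compositionality.
#'
#' @param mat Species x samples matrix (or `tax_profile`); needs >= 3
#'   samples and >= 2 species.
#' @return An `ordination_result`: list with `coordinates` (samples x
#'   components), `explained_variance` (non-increasing proportions), and
#'   `distance_kind = "robust_aitchison"`.
#' @export
rclr_pcoa <- function(mat) {
  if (inherits(mat, "tax_profile")) mat <- mat$matrix
  if (ncol(mat) < 3L) stop("need >= 3 samples")
  if (nrow(mat) < 2L) stop("need >= 2 species")
  x <- t(rclr_transform(mat))          # samples x species
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(coordinates = pc$x,
                 explained_variance = ev / sum(ev),
                 distance_kind = "robust_aitchison"),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat("PCoA (", x$distance_kind, "): ", nrow(x$coordinates), " samples, ",
      "PC1 ", sprintf("%.1f%%", 100 * x$explained_variance[1L]),
      " of variance\n", sep = "")
  invisible(x)
}

# One-sided Mann-Whitney p-value; exact distribution when both groups are
# small enough to enumerate and tie-free, normal approximation with tie
# correction otherwise.
.mw_pvalue <- function(x, y, alternative, exact_max = 12L) {
  use_exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !any(duplicated(c(x, y)))
  suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = use_exact,
                correct = TRUE)$p.value
  )
}

#' Classify species as lost/expanded in CD, UC or IBD
#'
#' Assigns every species in the analysis universe (median relative
#' abundance > 0 in at least one study group) to one of seven categories:
#' IBD/CD/UC_LOST, IBD/CD/UC_EXPANDED, or UNCHANGED. For each species, four
#' one-sided Mann-Whitney tests are run against Control: loss
#' (`alternative = "less"`: the IBD group's values are lower) for CD and
#' UC, and expansion (`alternative = "greater"`) for CD and UC.
#' Benjamini-Hochberg correction is applied separately within the loss
#' family and within the expansion family, each family spanning all
#' species x both group comparisons (set `family_scope = "per_comparison"`
#' to correct each of the four test columns on its own). A species
#' significant in both CD and UC within a family gets the IBD_ prefix; in
#' exactly one, that group's prefix; when loss and expansion categories
#' both apply, the one with the lower minimal adjusted p wins.
#'
#' @param mat Species x samples relative-abundance matrix (or
#'   `tax_profile`).
#' @param groups Character/factor per sample with levels Control, CD, UC
#'   (>= 2 samples each).
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @param family_scope `"family"` (default) or `"per_comparison"`.
#' @param exact_max Largest group size for exact Mann-Whitney p-values
#'   (default 12).
#' @return Data frame: `species`, `category`, and BH-adjusted
#'   `p_loss_cd`, `p_loss_uc`, `p_exp_cd`, `p_exp_uc`.
#' @export
classify_species <- function(mat, groups, alpha = 0.05,
                             family_scope = c("family", "per_comparison"),
                             exact_max = 12L) {
  if (inherits(mat, "tax_profile")) mat <- mat$matrix
  family_scope <- match.arg(family_scope)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(mat))
  for (g in c("Control", "CD", "UC")) {
    if (sum(groups == g) < 2L) stop("missing or underpopulated group: ", g)
  }
  med_by_group <- sapply(c("Control", "CD", "UC"), function(g)
    apply(mat[, groups == g, drop = FALSE], 1L, median))
  universe <- rownames(mat)[apply(med_by_group > 0, 1L, any)]
  if (length(universe) == 0L)
    stop("empty species universe: no species with positive group median")

  ctrl <- mat[universe, groups == "Control", drop = FALSE]
  p_raw <- matrix(NA_real_, length(universe), 4L,
                  dimnames = list(universe,
                                  c("p_loss_cd", "p_loss_uc",
                                    "p_exp_cd", "p_exp_uc")))
  for (g in c("CD", "UC")) {
    sub <- mat[universe, groups == g, drop = FALSE]
    for (s in seq_along(universe)) {
      x <- sub[s, ]; y <- ctrl[s, ]
      p_raw[s, paste0("p_loss_", tolower(g))] <-
        .mw_pvalue(x, y, "less", exact_max)
      p_raw[s, paste0("p_exp_", tolower(g))] <-
        .mw_pvalue(x, y, "greater", exact_max)
    }
  }

  p_adj <- p_raw
  if (family_scope == "family") {
    loss <- c(p_raw[, "p_loss_cd"], p_raw[, "p_loss_uc"])
    loss <- p.adjust(loss, "BH")
    p_adj[, "p_loss_cd"] <- loss[seq_along(universe)]
    p_adj[, "p_loss_uc"] <- loss[-seq_along(universe)]
    expn <- c(p_raw[, "p_exp_cd"], p_raw[, "p_exp_uc"])
    expn <- p.adjust(expn, "BH")
    p_adj[, "p_exp_cd"] <- expn[seq_along(universe)]
    p_adj[, "p_exp_uc"] <- expn[-seq_along(universe)]
  } else {
    for (j in 1:4) p_adj[, j] <- p.adjust(p_raw[, j], "BH")
  }

  pick <- function(cd_p, uc_p, prefix) {
    sig_cd <- cd_p < alpha; sig_uc <- uc_p < alpha
    if (sig_cd && sig_uc) paste0("IBD_", prefix)
    else if (sig_cd) paste0("CD_", prefix)
    else if (sig_uc) paste0("UC_", prefix)
    else NA_character_
  }
  category <- vapply(seq_along(universe), function(s) {
    loss_cat <- pick(p_adj[s, "p_loss_cd"], p_adj[s, "p_loss_uc"], "LOST")
    exp_cat <- pick(p_adj[s, "p_exp_cd"], p_adj[s, "p_exp_uc"], "EXPANDED")
    if (!is.na(loss_cat) && !is.na(exp_cat)) {
      min_loss <- min(p_adj[s, c("p_loss_cd", "p_loss_uc")])
      min_exp <- min(p_adj[s, c("p_exp_cd", "p_exp_uc")])
      if (min_loss <= min_exp) loss_cat else exp_cat
    } else if (!is.na(loss_cat)) loss_cat
    else if (!is.na(exp_cat)) exp_cat
    else "UNCHANGED"
  }, character(1))

  data.frame(species = universe, category = category,
             p_adj, row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman rank correlation with test
#'
#' Average ranks for ties; the p-value uses the exact null distribution for
#' n <= 10 (tie-free) and the t approximation otherwise.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need n >= 3 pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant input vector")
  use_exact <- n <= 10L && !any(duplicated(x)) && !any(duplicated(y))
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = use_exact))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Group-median abundance curve with arcsine transform
#'
#' Per-species, per-group median relative abundance, variance-stabilized as
#' `arcsin(sqrt(p))` with `p` the median as a proportion, and ordered by
#' the Control median (descending) — the layout used to display the
#' abundance distribution across the species universe.
#'
#' @param mat Species x samples matrix of percent relative abundances.
#' @param groups Group label per sample.
#' @return Data frame: `species`, one `median_<group>` and one
#'   `arcsine_<group>` column per group, ordered by Control median.
#' @export
group_median_curve <- function(mat, groups) {
  if (inherits(mat, "tax_profile")) mat <- mat$matrix
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(mat))
  glev <- unique(c("Control", sort(setdiff(unique(groups), "Control"))))
  glev <- intersect(glev, unique(groups))
  med <- vapply(glev, function(g)
    apply(mat[, groups == g, drop = FALSE], 1L, median),
    numeric(nrow(mat)))
  med <- matrix(med, nrow = nrow(mat),
                dimnames = list(rownames(mat), glev))
  p <- med / 100
  if (any(p < 0) || any(p > 1))
    stop("median proportions outside [0, 1]; are abundances in percent?")
  arc <- asin(sqrt(p))
  out <- data.frame(species = rownames(mat), stringsAsFactors = FALSE)
  for (g in glev) {
    out[[paste0("median_", g)]] <- med[, g]
    out[[paste0("arcsine_", g)]] <- arc[, g]
  }
  if ("Control" %in% glev)
    out <- out[order(-out$median_Control), ]
  rownames(out) <- NULL
  out
}
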