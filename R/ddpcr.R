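#' Absolute quantification from droplet counts
#'
#' Droplet digital PCR partitions the reaction into ~20,000 droplets; the
#' Poisson correction for multiple template copies per droplet gives
#' `lambda = -ln(negative/total)` mean copies per droplet, hence
#' `copies = lambda * total` per reaction. Each detected copy of a
#' single-copy human locus represents one genome equivalent, taken as
#' 3.3 pg of human DNA, so the human percentage of the assayed fecal DNA is
#' `copies * 3.3 pg / (input_mass_ng * 1000 pg) * 100`. A computed
#' percentage above 100 is capped at 100 and flagged saturated.
#'
#' @param d A [droplet_counts()] object.
#' @param input_mass_ng Fecal DNA mass in the reaction (default 5 ng).
#' @param genome_equiv_pg Mass of one genome equivalent (default 3.3 pg).
#' @return A `ddpcr_quant`: list with `lambda_per_droplet`, `copies`,
#'   `mass_pg`, `human_pct`, `input_mass_ng`, `saturated`.
#' @export
quantify_ddpcr <- function(d, input_mass_ng = 5, genome_equiv_pg = 3.3) {
  stopifnot(inherits(d, "droplet_counts"))
  if (d$total == 0L) stop("empty reaction: no droplets")
  if (d$negative == 0L)
    stop("saturated reaction: no negative droplets, copies unbounded")
  lambda <- -log(d$negative / d$total)
  copies <- lambda * d$total
  mass_pg <- copies * genome_equiv_pg
  human_pct <- mass_pg / (input_mass_ng * 1000) * 100
  saturated <- human_pct > 100
  if (saturated) human_pct <- 100
  structure(list(lambda_per_droplet = lambda, copies = copies,
                 mass_pg = mass_pg, human_pct = human_pct,
                 input_mass_ng = input_mass_ng, saturated = saturated),
            class = "ddpcr_quant")
}

#' @export
print.ddpcr_quant <- function(x, ...) {
  cat(sprintf("ddPCR: lambda=%.4g copies=%.4g mass=%.4g pg human=%.3g%%%s\n",
              x$lambda_per_droplet, x$copies, x$mass_pg, x$human_pct,
              if (x$saturated) " (saturated)" else ""))
  invisible(x)
}

#' Normalize methylation cell fractions to total fecal DNA
#'
#' Cell-type fractions from the methylation assay are fractions of the
#' *human* DNA; multiplying by the ddPCR human percentage expresses them as
#' percentages of total fecal DNA. Re-normalizing an already-normalized
#' profile is rejected.
#'
#' @param profile A `sample_methylation_profile` passing QC.
#' @param quant A `ddpcr_quant`.
#' @return The profile with `normalized_fraction` filled in.
#' @export
normalize_cell_fractions <- function(profile, quant) {
  stopifnot(inherits(profile, "sample_methylation_profile"),
            inherits(quant, "ddpcr_quant"))
  if (!profile$qc_pass)
    stop("profile failed QC (", profile$qc_reason, "); not normalizing")
  if (!is.null(profile$normalized_fraction))
    stop("profile is already normalized")
  profile$normalized_fraction <-
    profile$per_cell_type_fraction * quant$human_pct / 100
  profile
}

#' Quantify a table of droplet counts
#'
#' Vectorized convenience over [quantify_ddpcr()] for the TSV interface:
#' `sample_id, total, positive, negative` in; the same with `lambda`,
#' `copies`, `mass_pg`, `human_pct`, `saturated` appended out.
#'
#' @param droplets Data frame with columns `sample_id`, `total`,
#'   `positive`, `negative`.
#' @param input_mass_ng,genome_equiv_pg As in [quantify_ddpcr()].
#' @return Augmented data frame.
#' @export
quantify_ddpcr_table <- function(droplets, input_mass_ng = 5,
                                 genome_equiv_pg = 3.3) {
  stopifnot(all(c("sample_id", "total", "positive", "negative") %in%
                  names(droplets)))
  qs <- lapply(seq_len(nrow(droplets)), function(i) {
    quantify_ddpcr(droplet_counts(droplets$total[i], droplets$positive[i],
                                  droplets$negative[i]),
                   input_mass_ng, genome_equiv_pg)
  })
  droplets$lambda <- vapply(qs, `[[`, numeric(1), "lambda_per_droplet")
  droplets$copies <- vapply(qs, `[[`, numeric(1), "copies")
  droplets$mass_pg <- vapply(qs, `[[`, numeric(1), "mass_pg")
  droplets$human_pct <- vapply(qs, `[[`, numeric(1), "human_pct")
  droplets$saturated <- vapply(qs, `[[`, logical(1), "saturated")
  droplets
}
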