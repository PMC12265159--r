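#' Match a bisulfite read against a marker panel
#'
#' Similarity is percent identity of an ungapped, end-anchored comparison in
#' bisulfite space: a reference C outside CpG offsets matches a read C or T
#' (conversion may or may not have fired), the C of each CpG matches C
#' (methylated) or T (unmethylated), and every other position must match
#' literally. The comparison runs over the overlap of read and reference;
#' a read shorter than half of every reference is unmatchable. Reads whose
#' best similarity falls below `min_similarity` (default 80 percent, the
#' assay's filtering threshold) are reported as no-match. Ties go to the
#' first marker in panel order.
#'
#' @param read A single read sequence (character scalar).
#' @param panel A `marker_panel`.
#' @param min_similarity Minimum percent identity to accept (default 80).
#' @return List with `marker_id` and `similarity`, or `NULL` for no-match.
#' @export
match_read <- function(read, panel, min_similarity = 80) {
  stopifnot(is.character(read), length(read) == 1L, nzchar(read))
  m <- .match_reads(read, panel, min_similarity)
  if (is.na(m$marker_id[1L])) return(NULL)
  list(marker_id = m$marker_id[1L], similarity = m$similarity[1L])
}

# Vectorized matcher. Returns data.frame(marker_id, similarity) with NA
# marker_id for no-match. Reads are grouped by length so each group is a
# single character-matrix comparison per marker.
.match_reads <- function(reads, panel, min_similarity = 80) {
  if (!is.data.frame(panel) || nrow(panel) == 0L) stop("empty marker panel")
  n <- length(reads)
  res_marker <- rep(NA_character_, n)
  res_sim <- rep(NA_real_, n)
  refs <- lapply(panel$sequence, function(s) strsplit(s, "")[[1]])
  ref_lens <- lengths(refs)
  lens <- nchar(reads)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    M <- matrix(unlist(strsplit(reads[idx], ""), use.names = FALSE),
                nrow = length(idx), byrow = TRUE)
    sim <- matrix(-Inf, length(idx), nrow(panel))
    for (k in seq_len(nrow(panel))) {
      if (L < 0.5 * ref_lens[k]) next
      r <- refs[[k]]
      cmpL <- min(L, ref_lens[k])
      cpg_c <- panel$cpg_offsets[[k]] + 1L
      eq <- matrix(FALSE, length(idx), cmpL)
      for (j in seq_len(cmpL)) {
        if (r[j] == "C") {
          eq[, j] <- M[, j] == "C" | M[, j] == "T"
        } else {
          eq[, j] <- M[, j] == r[j]
        }
      }
      sim[, k] <- 100 * rowSums(eq) / cmpL
    }
    best <- max.col(sim, ties.method = "first")
    best_sim <- sim[cbind(seq_along(idx), best)]
    ok <- is.finite(best_sim) & best_sim >= min_similarity
    res_marker[idx[ok]] <- panel$marker_id[best[ok]]
    res_sim[idx[ok]] <- best_sim[ok]
  }
  data.frame(marker_id = res_marker, similarity = res_sim,
             stringsAsFactors = FALSE)
}

#' Call CpG methylation states on a matched read
#'
#' At each CpG offset the read dinucleotide is inspected: "CG" is called
#' methylated, "TG" unmethylated, anything else (including an offset beyond
#' the read end) ambiguous. Conversion QC checks the non-CpG cytosines of
#' the reference: the read should show T there; a read in which more than
#' `max_unconverted_frac` of those positions still read C failed bisulfite
#' conversion and is flagged.
#'
#' @param read Read sequence.
#' @param marker One row of a `marker_panel` (data frame row or list with
#'   `sequence` and `cpg_offsets`).
#' @param max_unconverted_frac Maximum tolerated fraction of unconverted
#'   non-CpG cytosines (default 0.10).
#' @return A `molecule_call`: list with `marker_id`, `cpg_states`
#'   (character vector over METH/UNMETH/AMBIG), and `conversion_ok`.
#' @export
call_cpgs <- function(read, marker, max_unconverted_frac = 0.10) {
  seqs <- if (is.data.frame(marker)) marker$sequence[1L] else marker$sequence
  offs <- if (is.data.frame(marker)) marker$cpg_offsets[[1L]] else marker$cpg_offsets
  mid <- if (is.data.frame(marker)) marker$marker_id[1L] else marker$marker_id
  ref <- strsplit(seqs, "")[[1]]
  rd <- strsplit(read, "")[[1]]
  L <- length(rd)
  states <- vapply(offs, function(o) {
    c1 <- o + 1L; g1 <- o + 2L
    if (g1 > L) return("AMBIG")
    di <- paste0(rd[c1], rd[g1])
    if (di == "CG") "METH" else if (di == "TG") "UNMETH" else "AMBIG"
  }, character(1))
  noncpg_c <- setdiff(which(ref == "C"), offs + 1L)
  noncpg_c <- noncpg_c[noncpg_c <= L]
  conv_ok <- TRUE
  if (length(noncpg_c) > 0L) {
    unconv <- mean(rd[noncpg_c] == "C")
    conv_ok <- unconv <= max_unconverted_frac
  }
  structure(list(marker_id = mid, cpg_states = states,
                 conversion_ok = conv_ok),
            class = "molecule_call")
}

#' Fraction of fully unmethylated molecules at one marker
#'
#' The fraction of tissue-specific DNA at a marker is the fraction of
#' molecules in which all CpG sites are unmethylated. Molecules with any
#' ambiguous site are excluded from numerator and denominator; calls that
#' failed conversion QC should already have been removed.
#'
#' @param calls List of `molecule_call` objects for a single marker.
#' @return List with `n` (molecules scored), `n_all_unmeth`, `fraction`
#'   (`0` with `empty = TRUE` when no molecule survives), and `empty` flag.
#' @export
marker_fraction <- function(calls) {
  if (length(calls) > 0L) {
    ids <- unique(vapply(calls, function(x) x$marker_id, character(1)))
    if (length(ids) > 1L)
      stop("calls span multiple markers: ", paste(ids, collapse = ", "))
  }
  keep <- vapply(calls, function(x) !any(x$cpg_states == "AMBIG"), logical(1))
  kept <- calls[keep]
  n <- length(kept)
  if (n == 0L) {
    warning("no unambiguous molecules at marker; fraction set to 0")
    return(list(n = 0L, n_all_unmeth = 0L, fraction = 0, empty = TRUE))
  }
  n_un <- sum(vapply(kept, function(x) all(x$cpg_states == "UNMETH"),
                     logical(1)))
  list(n = n, n_all_unmeth = n_un, fraction = n_un / n, empty = FALSE)
}

# Vectorized calling for all reads assigned to one marker.
# Returns list(states = matrix reads x cpgs over METH/UNMETH/AMBIG,
#              conversion_ok = logical).
.call_cpgs_matrix <- function(reads, ref_chars, offs, max_unconverted_frac) {
  n <- length(reads)
  lens <- nchar(reads)
  maxL <- max(lens)
  M <- matrix("", n, maxL)
  for (L in unique(lens)) {
    i <- which(lens == L)
    M[i, seq_len(L)] <- matrix(unlist(strsplit(reads[i], ""), use.names = FALSE),
                               nrow = length(i), byrow = TRUE)
  }
  states <- matrix("AMBIG", n, length(offs))
  for (j in seq_along(offs)) {
    c1 <- offs[j] + 1L; g1 <- offs[j] + 2L
    if (g1 > maxL) next
    in_range <- lens >= g1
    di_c <- M[, c1]; di_g <- M[, g1]
    states[in_range & di_c == "C" & di_g == "G", j] <- "METH"
    states[in_range & di_c == "T" & di_g == "G", j] <- "UNMETH"
  }
  noncpg_c <- setdiff(which(ref_chars == "C"), offs + 1L)
  conv_ok <- rep(TRUE, n)
  if (length(noncpg_c) > 0L) {
    sub <- M[, noncpg_c, drop = FALSE]
    in_read <- outer(lens, noncpg_c, ">=")
    n_eval <- rowSums(in_read)
    n_unconv <- rowSums((sub == "C") & in_read)
    conv_ok <- ifelse(n_eval == 0L, TRUE,
                      n_unconv / pmax(1L, n_eval) <= max_unconverted_frac)
  }
  list(states = states, conversion_ok = conv_ok)
}

#' Profile one sample: reads to per-cell-type DNA fractions
#'
#' Runs the full per-sample deconvolution: match every read to the panel at
#' `min_similarity`, discard reads failing conversion QC, call CpG states,
#' compute each marker's fully-unmethylated fraction (ambiguous molecules
#' excluded), and average markers within each cell type (unweighted by
#' default). Sample QC fails with reason `"low_reads"` when fewer than
#' `min_reads` reads survive the similarity filter, and with reason
#' `"fraction_sum"` when the summed cell-type fractions fall outside
#' `sum_bounds` (default 5-150 percent). Fractions are not renormalized to
#' 100 percent; the QC window operates on the raw sums. When
#' `ddpcr_human_pct` is supplied, fractions of human DNA are additionally
#' expressed as fractions of total fecal DNA.
#'
#' @param reads Character vector of read sequences (e.g. from
#'   [read_reads_fastq()]).
#' @param panel A `marker_panel`.
#' @param ddpcr_human_pct Optional percent of fecal DNA that is human, from
#'   the ddPCR assay; triggers normalization.
#' @param min_similarity Percent identity threshold (default 80).
#' @param min_reads Minimum retained reads for sample QC (default 1000).
#' @param max_unconverted_frac Conversion QC threshold (default 0.10).
#' @param sum_bounds Length-2 QC window for the summed cell-type fractions,
#'   in percent (default `c(5, 150)`).
#' @param weight_by_depth Weight markers by molecule count when averaging
#'   within a cell type (default FALSE, unweighted).
#' @return A `sample_methylation_profile`: list with `per_marker` (data
#'   frame), `per_cell_type_fraction` (named percent vector),
#'   `normalized_fraction` (or NULL), `total_reads`, `qc_pass`, `qc_reason`.
#' @export
aggregate_sample <- function(reads, panel, ddpcr_human_pct = NULL,
                             min_similarity = 80, min_reads = 1000L,
                             max_unconverted_frac = 0.10,
                             sum_bounds = c(5, 150),
                             weight_by_depth = FALSE) {
  validate_marker_panel(panel)
  matches <- .match_reads(reads, panel, min_similarity)
  retained <- !is.na(matches$marker_id)
  total_reads <- sum(retained)

  per_marker <- data.frame(
    marker_id = panel$marker_id, cell_type = panel$cell_type,
    n_matched = 0L, n_conversion_fail = 0L, n_ambig = 0L,
    n_molecules = 0L, n_fully_unmethylated = 0L, fraction = 0,
    empty = TRUE, stringsAsFactors = FALSE
  )
  for (k in seq_len(nrow(panel))) {
    sel <- which(retained & matches$marker_id == panel$marker_id[k])
    per_marker$n_matched[k] <- length(sel)
    if (length(sel) == 0L) next
    cc <- .call_cpgs_matrix(reads[sel],
                            strsplit(panel$sequence[k], "")[[1]],
                            panel$cpg_offsets[[k]], max_unconverted_frac)
    ok <- cc$conversion_ok
    per_marker$n_conversion_fail[k] <- sum(!ok)
    st <- cc$states[ok, , drop = FALSE]
    ambig <- apply(st == "AMBIG", 1L, any)
    per_marker$n_ambig[k] <- sum(ambig)
    st <- st[!ambig, , drop = FALSE]
    n <- nrow(st)
    per_marker$n_molecules[k] <- n
    if (n > 0L) {
      n_un <- sum(rowSums(st == "UNMETH") == ncol(st))
      per_marker$n_fully_unmethylated[k] <- n_un
      per_marker$fraction[k] <- n_un / n
      per_marker$empty[k] <- FALSE
    }
  }

  agg_fun <- if (weight_by_depth) {
    function(i) stats::weighted.mean(per_marker$fraction[i],
                                     pmax(per_marker$n_molecules[i], 0L))
  } else {
    function(i) mean(per_marker$fraction[i])
  }
  cts <- unique(panel$cell_type)
  per_ct <- vapply(cts, function(ct) {
    i <- which(per_marker$cell_type == ct)
    if (weight_by_depth && sum(per_marker$n_molecules[i]) == 0L)
      return(0)
    100 * agg_fun(i)
  }, numeric(1))

  qc_pass <- TRUE; qc_reason <- ""
  if (total_reads < min_reads) {
    qc_pass <- FALSE; qc_reason <- "low_reads"
  } else {
    s <- sum(per_ct)
    if (s < sum_bounds[1] || s > sum_bounds[2]) {
      qc_pass <- FALSE; qc_reason <- "fraction_sum"
    }
  }

  prof <- structure(list(
    per_marker = per_marker,
    per_cell_type_fraction = per_ct,
    normalized_fraction = NULL,
    total_reads = total_reads,
    qc_pass = qc_pass, qc_reason = qc_reason
  ), class = "sample_methylation_profile")
  if (!is.null(ddpcr_human_pct))
    prof$normalized_fraction <- per_ct * ddpcr_human_pct / 100
  prof
}

#' @export
print.sample_methylation_profile <- function(x, ...) {
  cat("Sample methylation profile:", x$total_reads, "retained reads;",
      if (x$qc_pass) "QC pass" else paste0("QC FAIL (", x$qc_reason, ")"), "\n")
  print(round(x$per_cell_type_fraction, 2))
  if (!is.null(x$normalized_fraction)) {
    cat("normalized to total fecal DNA (%):\n")
    print(signif(x$normalized_fraction, 3))
  }
  invisible(x)
}

#' Combine per-sample profiles into a cohort-level table
#'
#' @param profiles Named list of `sample_methylation_profile` objects.
#' @param normalized Use ddPCR-normalized fractions (default FALSE).
#' @return Data frame: one row per sample, columns `sample_id`,
#'   `total_reads`, `qc_pass`, `qc_reason`, then one column per cell type
#'   (percent).
#' @export
profiles_table <- function(profiles, normalized = FALSE) {
  stopifnot(length(profiles) > 0L, !is.null(names(profiles)))
  cts <- names(profiles[[1L]]$per_cell_type_fraction)
  rows <- lapply(names(profiles), function(s) {
    p <- profiles[[s]]
    fr <- if (normalized) p$normalized_fraction else p$per_cell_type_fraction
    if (is.null(fr)) fr <- setNames(rep(NA_real_, length(cts)), cts)
    cbind(data.frame(sample_id = s, total_reads = p$total_reads,
                     qc_pass = p$qc_pass, qc_reason = p$qc_reason,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fr[cts])))
  })
  do.call(rbind, rows)
}
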