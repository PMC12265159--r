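#' Generate a synthetic cell-type-specific methylation marker panel
#'
#' Builds a panel of amplicon reference sequences, each assigned to one cell
#' type, with a known set of CpG sites. Marker discovery in real assays
#' selects genomic regions carrying at least five CpG sites within a window
#' of at least 150 bp that are unmethylated specifically in the target cell
#' type; the generator mirrors that geometry. Each reference contains "CG"
#' dinucleotides exactly at the recorded offsets and nowhere else, so CpG
#' calls in downstream tests are unambiguous.
#'
#' @param n_cell_types Number of cell types in the panel.
#' @param markers_per_type Markers generated per cell type.
#' @param amplicon_len Reference length in bp (default 150, the minimal
#'   marker window).
#' @param n_cpgs CpG sites per marker (default 5, the minimal marker
#'   requirement).
#' @param cell_types Optional character vector of cell-type names; defaults
#'   to the canonical fecal-DNA panel (neutrophil, monocyte, B_cell, T_cell,
#'   colon, small_intestine, then generic names).
#' @param seed Integer seed; the seed fully determines the panel.
#' @return A `marker_panel`: data frame with columns `marker_id`,
#'   `cell_type`, `sequence` and `cpg_offsets` (list column of 0-based
#'   offsets of the C of each CpG, strictly increasing).
#' @export
generate_marker_panel <- function(n_cell_types, markers_per_type,
                                  amplicon_len = 150L, n_cpgs = 5L,
                                  cell_types = NULL, seed = 1L) {
  stopifnot(n_cell_types >= 1L, markers_per_type >= 1L,
            amplicon_len >= 1L, n_cpgs >= 1L)
  if (2L * n_cpgs > amplicon_len) {
    stop("infeasible panel: ", n_cpgs, " CpG sites cannot fit in ",
         amplicon_len, " bp (each CpG needs 2 bp)")
  }
  if (is.null(cell_types)) cell_types <- default_cell_types(n_cell_types)
  stopifnot(length(cell_types) == n_cell_types, !anyDuplicated(cell_types))

  set.seed(seed)
  n_markers <- n_cell_types * markers_per_type
  rows <- vector("list", n_markers)
  k <- 0L
  for (ct in cell_types) {
    for (j in seq_len(markers_per_type)) {
      k <- k + 1L
      offs <- .sample_cpg_offsets(amplicon_len, n_cpgs)
      seq_chars <- sample(c("A", "C", "G", "T"), amplicon_len, replace = TRUE)
      seq_chars[offs + 1L] <- "C"
      seq_chars[offs + 2L] <- "G"
      seq_chars <- .scrub_stray_cg(seq_chars, offs)
      rows[[k]] <- data.frame(
        marker_id = sprintf("%s_m%02d", ct, j),
        cell_type = ct,
        sequence = paste(seq_chars, collapse = ""),
        stringsAsFactors = FALSE
      )
      rows[[k]]$cpg_offsets <- list(offs)
    }
  }
  panel <- do.call(rbind, rows)
  class(panel) <- c("marker_panel", "data.frame")
  validate_marker_panel(panel)
  panel
}

# Draw n strictly increasing 0-based offsets with pairwise gap >= 2 so the
# planted CG dinucleotides cannot overlap. Standard stars-and-bars shift:
# sample distinct positions, then add i-1 to the i-th to enforce the gap.
.sample_cpg_offsets <- function(amplicon_len, n_cpgs) {
  slots <- amplicon_len - 1L - (n_cpgs - 1L)
  picks <- sort(sample.int(slots, n_cpgs))
  as.integer(picks + seq_len(n_cpgs) - 1L - 1L)
}

# Remove CG dinucleotides not at planted offsets (mutate the C to A; this
# cannot create a new CG because A is never the 5' base of one).
.scrub_stray_cg <- function(seq_chars, offs) {
  planted_c <- offs + 1L
  repeat {
    is_c <- seq_chars == "C"
    is_g <- c(seq_chars[-1L] == "G", FALSE)
    stray <- which(is_c & is_g)
    stray <- setdiff(stray, planted_c)
    if (length(stray) == 0L) break
    seq_chars[stray] <- "A"
  }
  seq_chars
}

#' Validate a marker panel
#'
#' Checks the panel invariants: unique marker ids, strictly increasing CpG
#' offsets, a "CG" dinucleotide at every offset, and at least one marker per
#' declared cell type.
#'
#' @param panel A `marker_panel`.
#' @return The panel, invisibly; errors on violation.
#' @export
validate_marker_panel <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("marker_id", "cell_type", "sequence", "cpg_offsets") %in%
                  names(panel)))
  if (anyDuplicated(panel$marker_id))
    stop("duplicated marker_id in panel")
  for (i in seq_len(nrow(panel))) {
    offs <- panel$cpg_offsets[[i]]
    if (length(offs) == 0L || any(diff(offs) <= 0L))
      stop("CpG offsets must be strictly increasing (marker ",
           panel$marker_id[i], ")")
    chars <- strsplit(panel$sequence[i], "")[[1]]
    if (any(offs + 2L > length(chars)) ||
        any(chars[offs + 1L] != "C") || any(chars[offs + 2L] != "G"))
      stop("reference lacks CG at a recorded offset (marker ",
           panel$marker_id[i], ")")
  }
  invisible(panel)
}

#' Write / read a marker panel as TSV
#'
#' The on-disk format has columns `marker_id`, `cell_type`, `sequence` and
#' `cpg_offsets` with the 0-based offsets semicolon-separated.
#'
#' @param panel A `marker_panel`.
#' @param path Output (or input) TSV path.
#' @return `write_marker_panel` returns `path` invisibly;
#'   `read_marker_panel` returns a `marker_panel`.
#' @export
write_marker_panel <- function(panel, path) {
  validate_marker_panel(panel)
  out <- data.frame(
    marker_id = panel$marker_id,
    cell_type = panel$cell_type,
    sequence = panel$sequence,
    cpg_offsets = vapply(panel$cpg_offsets, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_panel
#' @export
read_marker_panel <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$cpg_offsets <- lapply(strsplit(as.character(df$cpg_offsets), ";"),
                           function(x) as.integer(x))
  class(df) <- c("marker_panel", "data.frame")
  validate_marker_panel(df)
  df
}

#' Specify a ground-truth cell mixture
#'
#' A mixture specification is the ground truth behind a simulated sample:
#' the composition of the human DNA by cell type, and what percentage of the
#' total fecal DNA is human at all.
#'
#' @param cell_fractions Named numeric vector of cell-type fractions of the
#'   human DNA; must be non-negative and sum to 1 (tolerance 1e-9).
#' @param total_human_pct Percent of fecal DNA that is human, in \[0, 100\].
#' @return A `mixture_spec` object.
#' @export
mixture_spec <- function(cell_fractions, total_human_pct = 100) {
  stopifnot(is.numeric(cell_fractions), !is.null(names(cell_fractions)),
            all(cell_fractions >= 0))
  if (abs(sum(cell_fractions) - 1) > 1e-9)
    stop("cell_fractions must sum to 1 (got ", sum(cell_fractions), ")")
  if (total_human_pct < 0 || total_human_pct > 100)
    stop("total_human_pct must be in [0, 100]")
  structure(list(cell_fractions = cell_fractions,
                 total_human_pct = total_human_pct),
            class = "mixture_spec")
}
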