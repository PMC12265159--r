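# Small fixtures shared across test files; everything is built in code.

# Tiny panel with known sequences so expected bisulfite-space strings can
# be written down by hand.
tiny_panel <- function() {
  p <- data.frame(
    marker_id = c("neutrophil_m01", "colon_m01"),
    cell_type = c("neutrophil", "colon"),
    sequence = c("ACGTACGTCCA", "TTCGGACGATA"),
    stringsAsFactors = FALSE
  )
  # CG at 0-based offsets: marker 1 at 1 and 5; marker 2 at 2 and 6
  p$cpg_offsets <- list(c(1L, 5L), c(2L, 6L))
  class(p) <- c("marker_panel", "data.frame")
  fecalsig::validate_marker_panel(p)
  p
}

# Fully bisulfite-converted read for a marker: unmethylated CpGs (C -> T)
# and all non-CpG Cs converted.
converted_read <- function(panel, i, methylated = FALSE) {
  chars <- strsplit(panel$sequence[i], "")[[1]]
  cpg_c <- panel$cpg_offsets[[i]] + 1L
  conv <- which(chars == "C")
  if (methylated) conv <- setdiff(conv, cpg_c)
  chars[conv] <- "T"
  paste(chars, collapse = "")
}

# Independent brute-force reimplementation of the per-sample deconvolution
# using direct string loops; the oracle for end-to-end profile checks.
brute_force_profile <- function(reads, panel, min_similarity = 80,
                                max_unconverted_frac = 0.10) {
  score <- function(read, k) {
    r <- strsplit(panel$sequence[k], "")[[1]]
    s <- strsplit(read, "")[[1]]
    if (length(s) < 0.5 * length(r)) return(-Inf)
    L <- min(length(s), length(r))
    hits <- 0
    for (j in seq_len(L)) {
      ok <- if (r[j] == "C") s[j] %in% c("C", "T") else s[j] == r[j]
      hits <- hits + ok
    }
    100 * hits / L
  }
  frac <- setNames(numeric(nrow(panel)), panel$marker_id)
  nmol <- setNames(integer(nrow(panel)), panel$marker_id)
  nun <- setNames(integer(nrow(panel)), panel$marker_id)
  n_retained <- 0L
  for (read in reads) {
    sims <- vapply(seq_len(nrow(panel)), function(k) score(read, k),
                   numeric(1))
    best <- which.max(sims)
    if (!is.finite(sims[best]) || sims[best] < min_similarity) next
    n_retained <- n_retained + 1L
    r <- strsplit(panel$sequence[best], "")[[1]]
    s <- strsplit(read, "")[[1]]
    offs <- panel$cpg_offsets[[best]]
    # conversion QC on non-CpG reference cytosines within the read
    noncpg <- setdiff(which(r == "C"), offs + 1L)
    noncpg <- noncpg[noncpg <= length(s)]
    if (length(noncpg) > 0 &&
        mean(s[noncpg] == "C") > max_unconverted_frac) next
    states <- character(length(offs))
    for (q in seq_along(offs)) {
      c1 <- offs[q] + 1L; g1 <- offs[q] + 2L
      states[q] <- if (g1 > length(s)) "AMBIG"
      else if (s[c1] == "C" && s[g1] == "G") "METH"
      else if (s[c1] == "T" && s[g1] == "G") "UNMETH"
      else "AMBIG"
    }
    if (any(states == "AMBIG")) next
    id <- panel$marker_id[best]
    nmol[id] <- nmol[id] + 1L
    if (all(states == "UNMETH")) nun[id] <- nun[id] + 1L
  }
  for (id in panel$marker_id)
    frac[id] <- if (nmol[id] > 0) nun[id] / nmol[id] else 0
  list(fraction = frac, n_molecules = nmol, n_all_unmeth = nun,
       total_reads = n_retained)
}

# A molecule_call for tests without running the caller.
mk_call <- function(states, marker_id = "m1", conversion_ok = TRUE) {
  structure(list(marker_id = marker_id, cpg_states = states,
                 conversion_ok = conversion_ok), class = "molecule_call")
}

# Small cohort config used by several files (no reads: fast).
small_cohort <- function(seed = 1, ...) {
  fecalsig::simulate_cohort(fecalsig::cohort_config(
    n_per_group = c(Control = 12, CD = 12, UC = 12),
    include_reads = FALSE, seed = seed, ...))
}
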