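#' Simulate targeted bisulfite amplicon reads from a cell mixture
#'
#' Emits reads for every marker in the panel. Each read derives from one
#' molecule whose cell of origin is drawn from the mixture's cell fractions.
#' Methylation is all-or-none per molecule: a molecule originating from a
#' marker's own cell type is fully unmethylated at that marker's CpG sites
#' (which therefore read "TG" after conversion), any other origin is fully
#' methylated (CpGs read "CG"). Cytosines outside CpG sites are always
#' unmethylated and convert C to T with probability `conversion_rate` —
#' incomplete conversion is what the downstream conversion QC detects.
#' Uniform substitution errors are applied last. Ground-truth labels (marker
#' and cell of origin) are carried in the read names.
#'
#' @param panel A `marker_panel`.
#' @param mix A [mixture_spec()]; cell types absent from its names
#'   contribute no molecules.
#' @param reads_per_marker Reads simulated per marker. The targeted assay
#'   sequences to a total depth of about 10,000 reads per sample, so a
#'   sensible default is `10000 / nrow(panel)`.
#' @param conversion_rate Per-cytosine bisulfite conversion probability
#'   (default 0.99).
#' @param seq_error_rate Per-base uniform substitution error rate
#'   (default 0.001).
#' @param seed Integer seed.
#' @return Named character vector of read sequences; names are
#'   `r<index>|marker=<id>|cell=<origin>`.
#' @export
simulate_bisulfite_reads <- function(panel, mix,
                                     reads_per_marker = 1000L,
                                     conversion_rate = 0.99,
                                     seq_error_rate = 0.001,
                                     seed = 1L) {
  if (!is.data.frame(panel) || nrow(panel) == 0L)
    stop("empty marker panel")
  validate_marker_panel(panel)
  stopifnot(inherits(mix, "mixture_spec"),
            conversion_rate >= 0, conversion_rate <= 1,
            seq_error_rate >= 0, seq_error_rate <= 1,
            reads_per_marker >= 1L)
  set.seed(seed)
  fr <- mix$cell_fractions
  fr <- fr[fr > 0]
  out <- vector("list", nrow(panel))
  idx0 <- 0L
  for (i in seq_len(nrow(panel))) {
    ref <- strsplit(panel$sequence[i], "")[[1]]
    offs <- panel$cpg_offsets[[i]]
    n <- reads_per_marker
    origin <- if (length(fr) == 1L) rep(names(fr), n) else
      sample(names(fr), n, replace = TRUE, prob = fr)
    m <- matrix(rep(ref, each = n), nrow = n)
    cpg_c <- offs + 1L
    unmeth <- origin == panel$cell_type[i]
    if (any(unmeth)) m[unmeth, cpg_c] <- "T"
    noncpg_c <- setdiff(which(ref == "C"), cpg_c)
    if (length(noncpg_c) > 0L && conversion_rate > 0) {
      sub <- m[, noncpg_c, drop = FALSE]
      sub[runif(length(sub)) < conversion_rate] <- "T"
      m[, noncpg_c] <- sub
    }
    if (seq_error_rate > 0) {
      hit <- which(runif(length(m)) < seq_error_rate)
      if (length(hit) > 0L) {
        bases <- c("A", "C", "G", "T")
        repl <- bases[(match(m[hit], bases) - 1L +
                         sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L]
        m[hit] <- repl
      }
    }
    reads <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    names(reads) <- sprintf("r%07d|marker=%s|cell=%s",
                            idx0 + seq_len(n), panel$marker_id[i], origin)
    idx0 <- idx0 + n
    out[[i]] <- reads
  }
  unlist(out)
}

#' Write / read amplicon reads as FASTQ
#'
#' Reads are written with constant quality (Q40). The full read name,
#' including any ground-truth labels, is the FASTQ identifier.
#'
#' @param reads Named character vector of read sequences.
#' @param path FASTQ path (plain or `.gz`).
#' @return `write_reads_fastq` returns `path` invisibly; `read_reads_fastq`
#'   returns a named character vector.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Simulate droplet digital PCR partitioning
#'
#' Template molecules distribute over droplets following Poisson statistics:
#' a droplet is positive with probability `1 - exp(-copies/droplets)`.
#' The number of positive droplets is a single binomial draw.
#'
#' @param true_copies True template copies in the reaction (>= 0).
#' @param n_droplets Number of accepted droplets (> 0; typical reactions
#'   yield about 20,000).
#' @param seed Integer seed.
#' @return A `droplet_counts` object (fields `total`, `positive`,
#'   `negative`).
#' @export
simulate_ddpcr <- function(true_copies, n_droplets = 20000L, seed = 1L) {
  stopifnot(true_copies >= 0, n_droplets > 0)
  set.seed(seed)
  p_pos <- 1 - exp(-true_copies / n_droplets)
  pos <- rbinom(1L, n_droplets, p_pos)
  droplet_counts(n_droplets, pos)
}

#' Droplet count triple
#'
#' @param total Total accepted droplets.
#' @param positive Positive droplets.
#' @param negative Negative droplets; defaults to `total - positive`.
#' @return A `droplet_counts` object; errors unless
#'   `positive + negative == total` and all counts are non-negative.
#' @export
droplet_counts <- function(total, positive, negative = total - positive) {
  total <- as.integer(total); positive <- as.integer(positive)
  negative <- as.integer(negative)
  stopifnot(total >= 0, positive >= 0, negative >= 0)
  if (positive + negative != total)
    stop("droplet counts must satisfy positive + negative == total")
  structure(list(total = total, positive = positive, negative = negative),
            class = "droplet_counts")
}
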