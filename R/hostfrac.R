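#' Metagenomic human-read percentage
#'
#' @param total_reads,human_reads Integer vectors (recycled); human reads
#'   identified by alignment against the human genome before taxonomic
#'   classification.
#' @return `100 * human_reads / total_reads`, vectorized.
#' @export
human_read_pct <- function(total_reads, human_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be > 0")
  if (any(human_reads < 0) || any(human_reads > total_reads))
    stop("human_reads must be in [0, total_reads]")
  100 * human_reads / total_reads
}

#' Load a MetaPhlAn-style merged species table
#'
#' Parses a merged relative-abundance TSV (first column `clade_name`, one
#' column per sample, values percent). Only rows whose final rank token
#' starts with `s__` (species level, no strain `t__` suffix) are retained;
#' lineage prefixes are stripped. Comment lines starting `#` are skipped
#' (a leading `#clade_name` header is accepted).
#'
#' @param path TSV path.
#' @return A `tax_profile`: list with `matrix` (species x samples, percent)
#'   and `species_ids`. Attach read counts with [attach_read_counts()].
#' @export
load_taxprofile <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) | grepl("^#?clade_name", lines)
  first_data <- which(keep)[1L]
  if (is.na(first_data)) stop("malformed header: no clade_name table found")
  df <- read.delim(text = paste(lines[keep], collapse = "\n"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- sub("^#", "", names(df)[1L])
  if (names(df)[1L] != "clade_name")
    stop("malformed header: first column must be clade_name, got '",
         names(df)[1L], "'")
  tokens <- strsplit(df$clade_name, "|", fixed = TRUE)
  last <- vapply(tokens, function(x) x[length(x)], character(1))
  is_species <- grepl("^s__", last)
  if (!any(is_species)) {
    warning("no species-level rows in ", path)
    m <- matrix(numeric(0), 0L, ncol(df) - 1L,
                dimnames = list(NULL, names(df)[-1L]))
    return(structure(list(matrix = m, species_ids = character(0),
                          read_counts = NULL), class = "tax_profile"))
  }
  sp <- sub("^s__", "", last[is_species])
  if (anyDuplicated(sp)) {
    dup <- sp[duplicated(sp)][1L]
    line <- which(is_species)[which(duplicated(sp))[1L]]
    stop("duplicated species '", dup, "' (data row ", line, ")")
  }
  m <- as.matrix(df[is_species, -1L, drop = FALSE])
  if (any(is.na(m)) || any(m < 0)) {
    bad <- which(apply(is.na(m) | m < 0, 1L, any))[1L]
    stop("negative or missing abundance at data row ", which(is_species)[bad])
  }
  rownames(m) <- sp
  structure(list(matrix = m, species_ids = sp, read_counts = NULL),
            class = "tax_profile")
}

#' Construct a taxonomic profile from a matrix
#'
#' @param matrix Species x samples matrix of percent relative abundances.
#' @param read_counts Optional data frame with `sample_id`, `total_reads`,
#'   `human_reads` (and optionally `nonhuman_reads`).
#' @return A `tax_profile`.
#' @export
tax_profile <- function(matrix, read_counts = NULL) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            !is.null(colnames(matrix)), all(matrix >= 0))
  p <- structure(list(matrix = matrix, species_ids = rownames(matrix),
                      read_counts = NULL), class = "tax_profile")
  if (!is.null(read_counts)) p <- attach_read_counts(p, read_counts)
  p
}

#' @rdname tax_profile
#' @param profile A `tax_profile`.
#' @export
attach_read_counts <- function(profile, read_counts) {
  stopifnot(inherits(profile, "tax_profile"),
            all(c("sample_id", "total_reads", "human_reads") %in%
                  names(read_counts)))
  if (is.null(read_counts$nonhuman_reads))
    read_counts$nonhuman_reads <-
      read_counts$total_reads - read_counts$human_reads
  missing <- setdiff(colnames(profile$matrix), read_counts$sample_id)
  if (length(missing) > 0L)
    stop("read counts missing for samples: ", paste(missing, collapse = ", "))
  profile$read_counts <-
    read_counts[match(colnames(profile$matrix), read_counts$sample_id), ]
  profile
}

#' Subsample a profile to a fixed non-human read depth
#'
#' Control analysis for depth artifacts: species richness could in
#' principle track sequencing depth rather than biology. Per-sample species
#' read counts are reconstructed as relative abundance times non-human
#' reads (an approximation: the classifier reports relative abundances, not
#' counts), multinomially subsampled to `depth`, and renormalized. Samples
#' with fewer non-human reads than `depth` are dropped and listed in the
#' `dropped` attribute.
#'
#' @param profile A `tax_profile` with read counts attached.
#' @param depth Target non-human read depth (default 1,000,000).
#' @param seed Integer seed.
#' @return A `tax_profile` at the target depth, with attribute `dropped`
#'   naming excluded samples.
#' @export
subsample_nonhuman <- function(profile, depth = 1e6, seed = 1L) {
  stopifnot(inherits(profile, "tax_profile"))
  if (depth <= 0) stop("depth must be > 0")
  if (is.null(profile$read_counts))
    stop("profile has no read counts; use attach_read_counts()")
  set.seed(seed)
  nonhuman <- profile$read_counts$nonhuman_reads
  keep <- nonhuman >= depth
  dropped <- colnames(profile$matrix)[!keep]
  m <- profile$matrix[, keep, drop = FALSE]
  nh <- nonhuman[keep]
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(ncol(m))) {
    counts <- round(m[, i] / 100 * nh[i])
    if (sum(counts) == 0) next
    sub <- rmultinom(1L, size = depth, prob = counts)[, 1L]
    out[, i] <- 100 * sub / sum(sub)
  }
  res <- structure(list(matrix = out, species_ids = rownames(out),
                        read_counts = profile$read_counts[keep, ]),
                   class = "tax_profile")
  attr(res, "dropped") <- dropped
  res
}

#' @export
print.tax_profile <- function(x, ...) {
  cat("Taxonomic profile:", nrow(x$matrix), "species x",
      ncol(x$matrix), "samples",
      if (!is.null(x$read_counts)) "(read counts attached)" else "", "\n")
  invisible(x)
}
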