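test_that("matching works in bisulfite space with argmax and threshold", {
  panel <- tiny_panel()
  # fully converted read: 100% similarity to its own marker
  m <- match_read(converted_read(panel, 1), panel)
  expect_equal(m$marker_id, "neutrophil_m01")
  expect_equal(m$similarity, 100)
  # methylated molecule also matches at 100% (CpG C allowed)
  m2 <- match_read(converted_read(panel, 1, methylated = TRUE), panel)
  expect_equal(m2$similarity, 100)
  # unrelated random sequences fall below 80% essentially always
  set.seed(1)
  panel150 <- generate_marker_panel(1, 1, seed = 2)
  rand <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = ""),
    character(1))
  hits <- vapply(rand, function(r) !is.null(match_read(r, panel150)),
                 logical(1))
  expect_false(any(hits))
})

test_that("ties break by panel order and higher similarity wins", {
  p <- data.frame(marker_id = c("a_m1", "b_m1"), cell_type = c("a", "b"),
                  sequence = c("ACGTATTTTT", "ACGTATTTAA"),
                  stringsAsFactors = FALSE)
  p$cpg_offsets <- list(1L, 1L)
  class(p) <- c("marker_panel", "data.frame")
  # read equal to marker b: 100% to b beats 80% to a
  m <- match_read("ACGTATTTAA", p)
  expect_equal(m$marker_id, "b_m1")
  m2 <- match_read("ACGTATTTTT", p)
  expect_equal(m2$marker_id, "a_m1")
  # identical sequences: first in panel order wins the tie
  p$sequence[2] <- p$sequence[1]
  m3 <- match_read("ACGTATTTTT", p)
  expect_equal(m3$marker_id, "a_m1")
})

test_that("reads shorter than half of every reference are no-match", {
  panel <- generate_marker_panel(1, 1, seed = 4)
  frag <- substr(panel$sequence[1], 1, 70)  # < 50% of 150 bp
  expect_null(match_read(frag, panel, min_similarity = 0))
  frag2 <- substr(panel$sequence[1], 1, 80)  # >= 50%: eligible again
  expect_false(is.null(match_read(frag2, panel, min_similarity = 0)))
})

test_that("raising min_similarity never increases matched reads", {
  panel <- tiny_panel()
  set.seed(9)
  reads <- c(
    vapply(1:30, function(i) paste(sample(c("A", "C", "G", "T"), 11,
                                          replace = TRUE), collapse = ""),
           character(1)),
    rep(converted_read(panel, 1), 5), rep(converted_read(panel, 2), 5))
  n_matched <- function(thr)
    sum(!is.na(fecalsig:::.match_reads(reads, panel, thr)$marker_id))
  counts <- vapply(c(0, 20, 40, 60, 80, 100), n_matched, numeric(1))
  expect_equal(n_matched(0), length(reads))
  expect_true(all(diff(counts) <= 0))
})

test_that("CpG calling maps dinucleotides to states with AMBIG fallback", {
  panel <- tiny_panel()
  marker <- panel[1, ]
  call <- call_cpgs(converted_read(panel, 1), marker)
  expect_equal(unname(call$cpg_states), c("UNMETH", "UNMETH"))
  expect_true(call$conversion_ok)

  call2 <- call_cpgs(converted_read(panel, 1, methylated = TRUE), marker)
  expect_equal(unname(call2$cpg_states), c("METH", "METH"))

  # TA at a CpG is ambiguous; offset beyond read end is ambiguous
  r <- converted_read(panel, 1)
  substr(r, 6, 7) <- "TA"
  expect_equal(unname(call_cpgs(r, marker)$cpg_states), c("UNMETH", "AMBIG"))
  short <- substr(converted_read(panel, 1), 1, 6)
  expect_equal(unname(call_cpgs(short, marker)$cpg_states)[2], "AMBIG")

  # fully unconverted non-CpG cytosines fail conversion QC
  unconv <- panel$sequence[1]  # no C->T conversion at all
  expect_false(call_cpgs(unconv, marker)$conversion_ok)
})

test_that("marker_fraction counts fully unmethylated molecules", {
  calls <- c(replicate(3, mk_call(c("UNMETH", "UNMETH")), simplify = FALSE),
             replicate(7, mk_call(c("METH", "METH")), simplify = FALSE))
  mf <- marker_fraction(calls)
  expect_equal(mf$fraction, 0.3)
  expect_equal(mf$n, 10)

  all_un <- replicate(4, mk_call(c("UNMETH", "UNMETH")), simplify = FALSE)
  expect_equal(marker_fraction(all_un)$fraction, 1)

  ambig <- replicate(5, mk_call(c("UNMETH", "AMBIG")), simplify = FALSE)
  expect_warning(mf0 <- marker_fraction(ambig), "no unambiguous")
  expect_equal(mf0$n, 0)
  expect_equal(mf0$fraction, 0)
  expect_true(mf0$empty)

  # read order and duplication leave the fraction unchanged
  mixed <- c(all_un, ambig, calls)
  f1 <- marker_fraction(mixed)$fraction
  f2 <- marker_fraction(rev(mixed))$fraction
  f3 <- marker_fraction(c(mixed, mixed))$fraction
  expect_equal(f1, f2)
  expect_equal(f1, f3)
  expect_error(marker_fraction(list(mk_call("METH", "m1"),
                                    mk_call("METH", "m2"))), "multiple")
})

test_that("sample QC thresholds act exactly at their boundaries", {
  panel <- tiny_panel()
  r_un <- converted_read(panel, 1)
  # 999 retained reads fail, 1000 pass
  p999 <- aggregate_sample(rep(r_un, 999), panel)
  expect_false(p999$qc_pass)
  expect_equal(p999$qc_reason, "low_reads")
  # 1000 reads, all unmethylated at marker 1: cell sums 100% -> pass
  p1000 <- aggregate_sample(rep(r_un, 1000), panel)
  expect_true(p1000$qc_pass)
  # both markers fully unmethylated: sum = 200% > 150 -> fraction_sum
  both <- c(rep(converted_read(panel, 1), 600),
            rep(converted_read(panel, 2), 600))
  pboth <- aggregate_sample(both, panel)
  expect_false(pboth$qc_pass)
  expect_equal(pboth$qc_reason, "fraction_sum")
  # all methylated everywhere: sum = 0% < 5 -> fraction_sum
  meth <- c(rep(converted_read(panel, 1, methylated = TRUE), 600),
            rep(converted_read(panel, 2, methylated = TRUE), 600))
  pmeth <- aggregate_sample(meth, panel)
  expect_equal(pmeth$qc_reason, "fraction_sum")
})

test_that("ddPCR normalization multiplies fractions by the human percent", {
  panel <- tiny_panel()
  reads <- c(rep(converted_read(panel, 1), 400),
             rep(converted_read(panel, 1, methylated = TRUE), 600),
             rep(converted_read(panel, 2, methylated = TRUE), 500))
  prof <- aggregate_sample(reads, panel, ddpcr_human_pct = 10)
  expect_equal(unname(prof$per_cell_type_fraction["neutrophil"]), 40)
  expect_equal(unname(prof$normalized_fraction["neutrophil"]), 4)
})

test_that("end-to-end profile equals the brute-force oracle on tiny inputs", {
  panel <- tiny_panel()
  set.seed(21)
  for (rep_i in 1:5) {
    reads <- c(
      replicate(6, converted_read(panel, sample(1:2, 1),
                                  methylated = runif(1) < 0.5)),
      vapply(1:8, function(i) paste(sample(c("A", "C", "G", "T"), 11,
                                           replace = TRUE), collapse = ""),
             character(1)),
      # reads with a random base flipped
      vapply(1:6, function(i) {
        r <- converted_read(panel, sample(1:2, 1))
        pos <- sample(nchar(r), 1)
        substr(r, pos, pos) <- sample(c("A", "C", "G", "T"), 1)
        r
      }, character(1)))
    oracle <- brute_force_profile(reads, panel)
    got <- suppressWarnings(aggregate_sample(reads, panel, min_reads = 0))
    expect_equal(got$total_reads, oracle$total_reads)
    expect_equal(setNames(got$per_marker$fraction, got$per_marker$marker_id),
                 oracle$fraction)
    expect_equal(setNames(got$per_marker$n_molecules,
                          got$per_marker$marker_id),
                 oracle$n_molecules)
  }
})

test_that("recovered fractions match planted mixtures on clean reads", {
  panel <- generate_marker_panel(3, 1,
                                 cell_types = c("neutrophil", "colon",
                                                "B_cell"), seed = 12)
  mix <- mixture_spec(c(neutrophil = 0.6, colon = 0.25, B_cell = 0.15))
  reads <- simulate_bisulfite_reads(panel, mix, 10000, conversion_rate = 1,
                                    seq_error_rate = 0, seed = 13)
  prof <- aggregate_sample(reads, panel)
  for (ct in names(mix$cell_fractions)) {
    truth <- mix$cell_fractions[[ct]]
    se <- sqrt(truth * (1 - truth) / 10000)
    expect_lt(abs(prof$per_cell_type_fraction[[ct]] / 100 - truth), 3 * se)
  }
})
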