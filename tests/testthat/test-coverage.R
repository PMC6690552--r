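pep60 <- tibble::tibble(peptide_id = "pep", length_aa = 60L)

test_that("window depths equal hand-computed per-residue means", {
  # no hits: all-zero windows
  cov0 <- window_coverage(
    tibble::tibble(peptide_id = character(), subject_start = integer(),
                   subject_end = integer()),
    pep60, 30)
  expect_equal(cov0$depth, c(0, 0))
  expect_equal(cov0$n_residues, c(30L, 30L))

  # overlapping hits 1-20, 10-40, 31-60: windows hold 41/30 and 40/30
  hits <- tibble::tibble(peptide_id = "pep",
                         subject_start = c(1L, 10L, 31L),
                         subject_end = c(20L, 40L, 60L))
  cov <- window_coverage(hits, pep60, 30)
  expect_equal(cov$depth, c(41 / 30, 40 / 30))

  # trailing short window keeps its true residue count as denominator
  pep45 <- tibble::tibble(peptide_id = "pep", length_aa = 45L)
  cov45 <- window_coverage(
    tibble::tibble(peptide_id = "pep", subject_start = 1L,
                   subject_end = 45L),
    pep45, 30)
  expect_equal(cov45$depth, c(1, 1))
  expect_equal(cov45$n_residues, c(30L, 15L))
})

test_that("a hit outside the peptide bounds is rejected by name", {
  hits <- tibble::tibble(peptide_id = "pep", subject_start = 50L,
                         subject_end = 70L)
  expect_error(window_coverage(hits, pep60, 30), "pep:50-70")
})

test_that("window coverage matches the naive per-residue oracle", {
  withr::local_seed(101)
  for (rep in 1:200) {
    L <- sample(10:120, 1)
    win <- sample(c(7, 15, 30), 1)
    hits <- random_hit_set(L, sample(0:20, 1))
    got <- window_coverage(hits, tibble::tibble(peptide_id = "pep",
                                                length_aa = L), win)
    want <- oracle_window_depths(hits$subject_start, hits$subject_end,
                                 L, win)
    expect_equal(got$depth, want)
  }
})

test_that("normalization is per million mapped reads and scale-free", {
  cov <- tibble::tibble(peptide_id = "pep", window_index = 1L,
                        n_residues = 30L, depth = 2.0)
  expect_equal(normalize_coverage(cov, 1e6)$depth_norm, 2.0)
  a <- normalize_coverage(dplyr::mutate(cov, depth = depth * 7), 7e6)
  expect_equal(a$depth_norm, normalize_coverage(cov, 1e6)$depth_norm)
  expect_error(normalize_coverage(cov, 0), "positive")
})

test_that("mf_ratio takes the median ratio with degenerate-case flags", {
  mk <- function(d, total) normalize_coverage(tibble::tibble(
    peptide_id = "pep", window_index = seq_along(d),
    n_residues = 30L, depth = d), total)
  r <- mf_ratio(mk(c(12, 18, 24), 1e6), mk(c(9, 9, 12), 1e6))
  expect_equal(r$male_median_norm, 18)
  expect_equal(r$female_median_norm, 9)
  expect_equal(r$mf_ratio, 2)
  expect_equal(r$flag, "ok")

  # identical profiles -> ratio 1
  expect_equal(mf_ratio(mk(c(3, 5), 1e6), mk(c(3, 5), 1e6))$mf_ratio, 1)

  # even window count: median is the mean of the central pair
  r4 <- mf_ratio(mk(c(1, 2, 4, 8), 1e6), mk(c(1, 1, 1, 1), 1e6))
  expect_equal(r4$male_median_norm, 3)

  # female all zero -> infinite ratio, flagged
  rz <- mf_ratio(mk(c(5, 5), 1e6), mk(c(0, 0), 1e6))
  expect_equal(rz$mf_ratio, Inf)
  expect_equal(rz$flag, "female_zero")

  # both zero -> no_coverage
  rn <- mf_ratio(mk(c(0, 0), 1e6), mk(c(0, 0), 1e6))
  expect_equal(rn$flag, "no_coverage")
  expect_true(is.na(rn$mf_ratio))

  # mismatched grids rejected
  expect_error(mf_ratio(mk(c(1, 2), 1e6), mk(c(1, 2, 3), 1e6)),
               "window grids")
})

test_that("mf_ratio is invariant to rescaling one library", {
  withr::local_seed(7)
  d_m <- rpois(10, 40)
  d_f <- rpois(10, 20)
  mk <- function(d, total) normalize_coverage(tibble::tibble(
    peptide_id = "pep", window_index = seq_along(d),
    n_residues = 30L, depth = d), total)
  base <- mf_ratio(mk(d_m, 1e6), mk(d_f, 2e6))$mf_ratio
  scaled <- mf_ratio(mk(d_m * 13, 13e6), mk(d_f, 2e6))$mf_ratio
  expect_equal(scaled, base)
})

test_that("Y-amplification calls require the cutoff AND an X-linked parent", {
  ratios <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    male_median_norm = c(1, 3, 3, 5, 0),
    female_median_norm = c(1, 1, 1, 0, 0),
    mf_ratio = c(1, 3, 3, Inf, NA),
    flag = c("ok", "ok", "ok", "female_zero", "no_coverage")
  )
  linkage <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    parent_linkage = c("X", "X", "autosome", "X")
  )
  calls <- call_y_amplified(ratios, linkage, cutoff = 2.5)
  expect_equal(calls$y_amplified, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(calls$status,
               c("not_amplified", "y_amplified", "not_amplified",
                 "y_specific_candidate", "no_coverage"))
  # unknown linkage reported, never called
  expect_equal(calls$parent_linkage[5], "unknown")
})

test_that("a ratio exactly at the cutoff is called (>= convention)", {
  ratios <- tibble::tibble(gene_id = "g", male_median_norm = 2.5,
                           female_median_norm = 1, mf_ratio = 2.5,
                           flag = "ok")
  linkage <- tibble::tibble(gene_id = "g", parent_linkage = "X")
  expect_true(call_y_amplified(ratios, linkage, 2.5)$y_amplified)
})

test_that("cutoff sweep thresholds ratios and validates input", {
  calls <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    mf_ratio = c(2.6, 6.0, 11.0),
    flag = "ok", parent_linkage = "X"
  )
  sw <- cutoff_sweep(calls, c(2.5, 5, 10))
  expect_equal(sw$n_called, c(3L, 2L, 1L))
  expect_true(all(diff(sw$n_called) <= 0))

  low <- dplyr::mutate(calls, mf_ratio = mf_ratio / 100)
  expect_equal(cutoff_sweep(low, c(2.5, 5, 10))$n_called, c(0L, 0L, 0L))

  expect_error(cutoff_sweep(calls, numeric(0)), "non-empty")
  expect_error(cutoff_sweep(calls, c(2.5, 2.5)), "distinct")
})
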