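test_that("identical seeds give identical cohorts and files", {
  cfg <- sim_config()
  a <- simulate_cohort(cfg, seed = 5)
  b <- simulate_cohort(cfg, seed = 5)
  expect_identical(a, b)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(a, d1)
  write_cohort(b, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  c2 <- simulate_cohort(cfg, seed = 6)
  expect_false(identical(a$hits_male, c2$hits_male))
})

test_that("zero depth yields empty hit tables but truth is still written", {
  genes <- demo_gene_table()[1:3, ]
  co <- simulate_cohort(tiny_config(genes, depth_male = 0,
                                    depth_female = 0), seed = 1)
  expect_equal(nrow(co$hits_male), 0L)
  expect_equal(nrow(co$hits_female), 0L)
  expect_equal(nrow(co$truth), 3L)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  expect_true(file.exists(file.path(d, "truth.json")))
})

test_that("every emitted file parses with the package readers, warning-free", {
  co <- simulate_cohort(sim_config(), seed = 9)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  expect_no_warning({
    hm <- read_alignment_hits(file.path(d, "hits_male.tsv"), "translated")
    hf <- read_alignment_hits(file.path(d, "hits_female.tsv"), "translated")
    hn <- read_alignment_hits(file.path(d, "hits_nucleotide.tsv"),
                              "nucleotide")
    gm <- read_gene_models(file.path(d, "gene_models.tsv"))
    sc <- read_scaffold_coverage(file.path(d, "scaffold_coverage.tsv"))
    st <- read_stranded_counts(file.path(d, "stranded_counts.tsv"))
  })
  expect_equal(nrow(hm), nrow(co$hits_male))
  expect_equal(nrow(hn), nrow(co$nucleotide_hits))
  expect_equal(gm$cds_length_bp, co$gene_models$cds_length_bp)
  expect_equal(nrow(sc), nrow(co$scaffold_coverage))
  expect_equal(nrow(st), nrow(co$stranded_counts))
  # strand-normalized nucleotide coordinates survive the round trip
  expect_equal(dplyr::arrange(hn, subject_id, subject_start, query_id),
               dplyr::arrange(co$nucleotide_hits, subject_id,
                              subject_start, query_id))
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    pep <- read_peptides(file.path(d, "peptides.fasta"))
    expect_equal(pep$length_aa, co$peptides$length_aa)
  }
})

test_that("truth JSON round-trips and rejects tampered schemas", {
  co <- simulate_cohort(tiny_config(demo_gene_table()[1:4, ]), seed = 3)
  tf <- withr::local_tempfile(fileext = ".json")
  write_truth(co$truth, tf)
  back <- read_truth(tf)
  expect_equal(back, co$truth)
  # tamper: drop a required field
  x <- jsonlite::read_json(tf, simplifyVector = TRUE)
  x$n_y <- NULL
  jsonlite::write_json(x, tf, auto_unbox = TRUE)
  expect_error(read_truth(tf), "schema")
  expect_error(read_truth(file.path(tempdir(), "nope_truth.json")))
})

test_that("per-gene expected coverage follows the copy-number model", {
  # nX=1, nY=0: expected M/F 0.5; nX=1, nY=4: expected 2.5; nA=1: 1.0;
  # Monte-Carlo means over 200 tiny replicate cohorts within 3 SE
  genes <- tibble::tibble(
    gene_id = c("x1", "xy4", "a1"), length_aa = 600L,
    n_x = c(1L, 1L, 0L), n_y = c(0L, 4L, 0L), n_a = c(0L, 0L, 1L),
    class = "anchor"
  )
  cfg <- tiny_config(genes, background_reads = 1e6)
  ratios <- purrr::map(1:200, function(s) {
    co <- simulate_cohort(cfg, seed = 1000 + s)
    cm <- normalize_coverage(window_coverage(co$hits_male, co$peptides),
                             co$male_total)
    cf <- normalize_coverage(window_coverage(co$hits_female, co$peptides),
                             co$female_total)
    mf_ratio(cm, cf)[, c("gene_id", "mf_ratio")]
  })
  r <- dplyr::bind_rows(ratios)
  for (spec in list(list(id = "x1", mu = 0.5), list(id = "xy4", mu = 2.5),
                    list(id = "a1", mu = 1.0))) {
    v <- r$mf_ratio[r$gene_id == spec$id]
    se <- stats::sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - spec$mu), 3 * se + 1e-9,
              label = sprintf("%s mean %.4f vs %.2f (SE %.4f)",
                              spec$id, mean(v), spec$mu, se))
  }
})

test_that("expected mf_ratio is monotone in Y copy number", {
  genes <- tibble::tibble(
    gene_id = sprintf("ny%02d", c(0, 2, 4, 8, 16)), length_aa = 450L,
    n_x = 1L, n_y = c(0L, 2L, 4L, 8L, 16L), n_a = 0L, class = "mono"
  )
  cfg <- tiny_config(genes, background_reads = 1e6)
  acc <- purrr::map(1:200, function(s) {
    co <- simulate_cohort(cfg, seed = 2000 + s)
    cm <- normalize_coverage(window_coverage(co$hits_male, co$peptides),
                             co$male_total)
    cf <- normalize_coverage(window_coverage(co$hits_female, co$peptides),
                             co$female_total)
    mf_ratio(cm, cf)[, c("gene_id", "mf_ratio")]
  })
  means <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(acc), gene_id),
    m = mean(mf_ratio), .groups = "drop")
  means <- means[order(means$gene_id), ]  # ny00 < ny02 < ... by name
  expect_true(all(diff(means$m) > 0))
})

test_that("invalid configurations are rejected", {
  genes <- demo_gene_table()
  expect_error(sim_config(genes = dplyr::mutate(genes, n_x = -1L)),
               "copy numbers")
  expect_error(sim_config(genes = genes[c(1, 1), ]), "unique")
  g0 <- dplyr::mutate(genes[1, ], n_x = 0L, n_y = 0L, n_a = 0L)
  expect_error(sim_config(genes = g0), "at least one genomic copy")
})
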