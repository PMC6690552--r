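single_exon_gene <- function(gene_id = "g1", len = 1000L,
                             scaffold = "sX1", start = 5000L,
                             strand = "+") {
  validate_gene_models(tibble::tibble(
    gene_id = gene_id, scaffold_id = scaffold, strand = strand,
    exon_start = start, exon_end = start + len - 1L
  ))
}

nuc_hit <- function(gene, exon_rank, qs, qe, scaffold, ss, se,
                    evalue = 1e-180) {
  tibble::tibble(
    query_id = exon_query_id(gene, exon_rank), subject_id = scaffold,
    pct_identity = 100, align_len = qe - qs + 1L, mismatches = 0L,
    gap_opens = 0L, query_start = qs, query_end = qe,
    subject_start = ss, subject_end = se, evalue = evalue, bitscore = 100
  )
}

test_that("the E-value filter is a hard <= 1e-20 threshold", {
  hits <- dplyr::bind_rows(
    nuc_hit("g1", 1L, 1L, 100L, "s1", 1L, 100L, evalue = 1e-19),
    nuc_hit("g1", 1L, 1L, 100L, "s1", 1L, 100L, evalue = 1e-20),
    nuc_hit("g1", 1L, 1L, 100L, "s1", 1L, 100L, evalue = 0)
  )
  kept <- filter_nucleotide_hits(hits)
  expect_equal(kept$evalue, c(1e-20, 0))
  expect_equal(nrow(filter_nucleotide_hits(hits[0, ])), 0L)
})

test_that("loci merge by reciprocal overlap and split by scaffold", {
  h <- dplyr::bind_rows(
    nuc_hit("g1", 1L, 1L, 600L, "s1", 100L, 700L),
    nuc_hit("g1", 1L, 1L, 500L, "s1", 150L, 650L)
  )
  h$gene_id <- "g1"
  loci <- resolve_loci(h)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$start, 100)
  expect_equal(loci$end, 700)

  h2 <- dplyr::bind_rows(
    nuc_hit("g1", 1L, 1L, 600L, "s1", 100L, 700L),
    nuc_hit("g1", 1L, 1L, 600L, "s2", 100L, 700L)
  )
  h2$gene_id <- "g1"
  expect_equal(nrow(resolve_loci(h2)), 2L)

  h3 <- nuc_hit("g1", 1L, 1L, 600L, "s1", 100L, 700L)
  h3$gene_id <- "g1"
  l3 <- resolve_loci(h3)
  expect_equal(nrow(l3), 1L)
  expect_equal(c(l3$start, l3$end), c(100, 700))
})

test_that("locus clustering matches the transitive-closure oracle", {
  withr::local_seed(202)
  for (rep in 1:100) {
    k <- sample(1:8, 1)
    sc <- sample(c("s1", "s2"), k, replace = TRUE)
    s <- sample.int(500, k, replace = TRUE)
    e <- s + sample.int(300, k, replace = TRUE)
    h <- tibble::tibble(gene_id = "g", subject_id = sc,
                        subject_start = s, subject_end = e)
    got <- assign_hit_loci(h, 0.5)
    want <- oracle_locus_clusters(got$subject_id, got$subject_start,
                                  got$subject_end, 0.5)
    # same partition (ids may differ)
    expect_equal(length(unique(got$locus_id)), length(unique(want)))
    expect_true(all(tapply(want, got$locus_id,
                           function(v) length(unique(v)) == 1)))
  }
})

test_that("duplication fraction implements the >= 25% two-location rule", {
  g <- single_exon_gene(len = 1000L)
  # locus A spans the whole parent, locus B covers CDS 301-1000 elsewhere
  dup30 <- dplyr::bind_rows(
    nuc_hit("g1", 1L, 1L, 600L, "sX1", 5000L, 5599L),
    nuc_hit("g1", 1L, 301L, 1000L, "sX9", 100000L, 100699L)
  )
  call <- call_x_duplicated(dup30, g)
  expect_equal(call$dup_fraction, 0.30)
  expect_true(call$x_duplicated)

  dup20 <- dplyr::bind_rows(
    nuc_hit("g1", 1L, 1L, 600L, "sX1", 5000L, 5599L),
    nuc_hit("g1", 1L, 401L, 1000L, "sX9", 100000L, 100599L)
  )
  call2 <- call_x_duplicated(dup20, g)
  expect_equal(call2$dup_fraction, 0.20)
  expect_false(call2$x_duplicated)

  # a single full-length locus is one location only
  one <- nuc_hit("g1", 1L, 1L, 1000L, "sX1", 5000L, 5999L)
  call3 <- call_x_duplicated(one, g)
  expect_equal(call3$dup_fraction, 0)
  expect_false(call3$x_duplicated)
  expect_equal(call3$n_loci_max_cov, 1L)
})

test_that("adding a hit never decreases the duplication fraction", {
  withr::local_seed(303)
  g <- single_exon_gene(len = 200L)
  hits <- NULL
  last <- 0
  for (i in 1:6) {
    qs <- sample.int(150, 1)
    qe <- qs + sample.int(200 - qs + 1, 1) - 1L
    new <- nuc_hit("g1", 1L, qs, qe, paste0("s", i),
                   100000L + i * 5000L, 100000L + i * 5000L + (qe - qs))
    hits <- dplyr::bind_rows(hits, new)
    frac <- call_x_duplicated(hits, g)$dup_fraction
    expect_gte(frac, last)
    expect_true(frac >= 0 && frac <= 1)
    last <- frac
  }
})

test_that("per-base counting matches the bitmap oracle on random instances", {
  withr::local_seed(404)
  for (rep in 1:100) {
    L <- sample(50:200, 1)
    g <- single_exon_gene(len = L)
    k <- sample(1:6, 1)
    hits <- purrr::map(seq_len(k), function(i) {
      qs <- sample.int(L, 1)
      qe <- qs + sample.int(L - qs + 1, 1) - 1L
      sc <- sample(c("sX1", "sA", "sB"), 1)
      ss <- sample.int(200000L, 1)
      nuc_hit("g1", 1L, qs, qe, sc, ss, ss + (qe - qs))
    })
    hits <- dplyr::bind_rows(hits)
    got <- call_x_duplicated(hits, g)
    mapped <- map_query_to_cds(normalize_hit_strand(hits), g)
    mapped <- assign_hit_loci(mapped)
    want <- oracle_dup_fraction(L, mapped$locus_id, mapped$cds_start,
                                mapped$cds_end)
    expect_equal(got$dup_fraction, want)
  }
})

test_that("exon-to-CDS mapping honours strand", {
  # minus-strand gene: exon ranks reversed, so exon1 is the rightmost
  g <- validate_gene_models(tibble::tibble(
    gene_id = "g1", scaffold_id = "s1", strand = "-",
    exon_start = c(1000L, 2000L), exon_end = c(1299L, 2399L)
  ))
  expect_equal(g$exon_rank, c(2L, 1L))
  h <- nuc_hit("g1", 1L, 1L, 400L, "s1", 2399L, 2000L)  # minus-strand hit
  mapped <- map_query_to_cds(normalize_hit_strand(h), g)
  expect_equal(mapped$cds_start, 1)
  expect_equal(mapped$cds_end, 400)
  h2 <- nuc_hit("g1", 2L, 1L, 300L, "s1", 1000L, 1299L)
  mapped2 <- map_query_to_cds(normalize_hit_strand(h2), g)
  expect_equal(mapped2$cds_start, 401)
  expect_equal(mapped2$cds_end, 700)

  # out-of-exon query interval rejected
  expect_error(
    map_query_to_cds(normalize_hit_strand(
      nuc_hit("g1", 1L, 1L, 500L, "s1", 2000L, 2399L)), g),
    "outside its exon")
})

test_that("excluding the parent locus changes the boundary verdict", {
  g <- single_exon_gene(len = 1000L)
  hits <- dplyr::bind_rows(
    nuc_hit("g1", 1L, 1L, 1000L, "sX1", 5000L, 5999L),   # parent
    nuc_hit("g1", 1L, 1L, 300L, "sX9", 100000L, 100299L) # partial dup
  )
  with_parent <- call_x_duplicated(hits, g)
  without <- call_x_duplicated(hits, g, exclude_parent_locus = TRUE)
  expect_equal(with_parent$dup_fraction, 0.30)
  expect_equal(without$dup_fraction, 0.30)
  # only the parent locus -> nothing duplicated once it is excluded
  solo <- call_x_duplicated(hits[1, ], g, exclude_parent_locus = TRUE)
  expect_equal(solo$dup_fraction, 0)
})

test_that("synthetic cohorts separate multi-copy from single-copy X genes", {
  genes <- dplyr::bind_rows(
    tibble::tibble(gene_id = sprintf("dup%02d", 1:10), length_aa = 300L,
                   n_x = 2L, n_y = 0L, n_a = 0L, class = "dup"),
    tibble::tibble(gene_id = sprintf("sgl%02d", 1:10), length_aa = 300L,
                   n_x = 1L, n_y = 0L, n_a = 0L, class = "single")
  )
  co <- simulate_cohort(tiny_config(genes), seed = 11)
  calls <- call_x_duplicated(co$nucleotide_hits, co$gene_models)
  j <- dplyr::inner_join(calls, co$truth, by = "gene_id")
  expect_true(all(j$x_duplicated[j$n_x >= 2]))
  expect_false(any(j$x_duplicated[j$n_x == 1]))
})
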