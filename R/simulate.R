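# Seeded synthetic-data generator. Emulates a male/female genomic
# resequencing design over a peptide reference: gene families with
# configured X/Y/autosomal copy numbers sequenced at Poisson depth
# proportional to copy number, scaffolds with Muller-element gene content
# and sex linkage (including a neo-X fusion), exact self-alignment
# nucleotide hit tables for every assembled copy, and stranded testis
# expression with configurable antisense fractions and small-RNA yields.
#
# Depth model: per-copy per-residue depth d (default 20x); a male library
# samples a gene at rate d * (nX + nY + 2 nA), a female at
# d * (2 nX + 2 nA), so the expected normalized M/F ratio is
# (nX + nY + 2 nA) / (2 nX + 2 nA). Hits are read-sized intervals
# (default 30 aa, ~100 bp translated) placed uniformly along the peptide.

#' Demo gene cohort: 60 genes in three classes
#'
#' 20 co-amplified genes (2-3 X copies, 12-32 Y copies, chosen so the
#' expected M/F ratio is at least 3 — amplification strong enough to be
#' detectable at the 2.5 cutoff), 20 Y-amplified-only genes (single X copy,
#' 8-32 Y copies), 10 single-copy X-linked and 10 single-copy autosomal
#' genes.
#'
#' @return A tibble with `gene_id`, `length_aa`, `n_x`, `n_y`, `n_a`,
#'   `class`.
#' @export
demo_gene_table <- function() {
  coamp <- tibble(
    gene_id = sprintf("gco%02d", 1:20),
    length_aa = rep(c(240, 300, 360, 420), 5),
    n_x = rep(c(2L, 3L), each = 10),
    n_y = c(12L, 14L, 16L, 18L, 20L, 22L, 24L, 26L, 28L, 32L,
            16L, 18L, 20L, 22L, 24L, 26L, 28L, 30L, 31L, 32L),
    n_a = 0L,
    class = "coamplified"
  )
  yonly <- tibble(
    gene_id = sprintf("gyo%02d", 1:20),
    length_aa = rep(c(270, 330, 390, 450), 5),
    n_x = 1L,
    n_y = c(8L, 9L, 10L, 12L, 13L, 14L, 16L, 17L, 18L, 20L,
            21L, 22L, 24L, 25L, 26L, 28L, 29L, 30L, 31L, 32L),
    n_a = 0L,
    class = "y_only"
  )
  xsingle <- tibble(
    gene_id = sprintf("gxs%02d", 1:10),
    length_aa = rep(c(250, 310, 370, 430, 490), 2),
    n_x = 1L, n_y = 0L, n_a = 0L,
    class = "single_copy_X"
  )
  asingle <- tibble(
    gene_id = sprintf("gas%02d", 1:10),
    length_aa = rep(c(260, 320, 380, 440, 500), 2),
    n_x = 0L, n_y = 0L, n_a = 1L,
    class = "single_copy_A"
  )
  bind_rows(coamp, yonly, xsingle, asingle)
}

#' Demo scaffold layout: five Muller elements, a neo-X and Y contigs
#'
#' Element A is the ancestral X; B, C and E are autosomal; D is a neo-X
#' (ancestrally autosomal, X-linked by coverage — an X-autosome fusion).
#' Eight Y contigs carry no Muller-labelled genes. Three sub-5 kb autosomal
#' scaffolds exercise the length filter.
#'
#' @return A tibble with `scaffold_id`, `element`, `linkage_class`,
#'   `length_bp`.
#' @export
demo_scaffold_table <- function() {
  mk <- function(prefix, element, linkage, n, len_min, len_max) {
    tibble(
      scaffold_id = sprintf("%s_%02d", prefix, seq_len(n)),
      element = element, linkage_class = linkage,
      length_bp = as.integer(round(seq(len_min, len_max, length.out = n)))
    )
  }
  bind_rows(
    mk("scafA", "A", "X", 14, 12000, 40000),
    mk("scafD", "D", "X", 14, 12000, 40000),
    mk("scafB", "B", "autosome", 12, 10000, 36000),
    mk("scafC", "C", "autosome", 12, 10000, 36000),
    mk("scafE", "E", "autosome", 12, 10000, 36000),
    mk("scafY", NA_character_, "Y", 8, 8000, 20000),
    mk("scafSm", "B", "autosome", 3, 2000, 4500)
  )
}

#' Simulation configuration
#'
#' Bundles the generator's parameters with defaults that emulate a
#' single-male / single-female Illumina resequencing design: per-copy
#' genomic depth 20x per sex, 30-aa read footprint, a 2e7-read autosomal
#' background per genomic library (so total-mapped-read normalization is
#' exercised but not distorted by the cohort itself), 10x per-copy
#' scaffold depth with 100-bp reads, and testis expression with
#' "conflict" genes (co-amplified class: antisense fraction 0.9, small-RNA
#' RPKM 300) against a background of sense-dominated genes.
#'
#' @param genes Gene cohort tibble (see [demo_gene_table()]).
#' @param scaffolds Scaffold layout tibble (see [demo_scaffold_table()]).
#' @param depth_male,depth_female Expected reads per residue per haploid
#'   copy in the male/female genomic library (default 20).
#' @param read_len_aa Translated read footprint in residues (default 30).
#' @param background_reads Expected autosomal background reads added to
#'   each genomic library total (default 2e7).
#' @param scaffold_depth Per-copy per-bp coverage for scaffold read counts
#'   (default 10).
#' @param scaffold_read_len_bp Genomic read length for scaffold counts
#'   (default 100).
#' @param y_divergence Per-residue substitution proportion applied to the
#'   reported percent identity of Y-copy reads (default 0, i.e. Y copies
#'   identical to the parent peptide).
#' @param expression Named list of per-class expression specs, each with
#'   `sense_rpkm`, `antisense_fraction`, `smallrna_rpkm`; classes absent
#'   from the list use `background`.
#' @param rna_total,smallrna_total Library totals for the stranded RNA and
#'   small-RNA libraries (defaults 2e7 and 1e7).
#' @param votes_per_scaffold Muller-labelled homology genes per scaffold
#'   used for element voting (default 6, one dissenting label on every
#'   third scaffold).
#' @param ancestral_x,autosomal_elements Element sets echoed to the
#'   pipeline (defaults `"A"` and `c("B","C","E")`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(genes = demo_gene_table(),
                       scaffolds = demo_scaffold_table(),
                       depth_male = 20, depth_female = 20,
                       read_len_aa = 30,
                       background_reads = 2e7,
                       scaffold_depth = 10,
                       scaffold_read_len_bp = 100,
                       y_divergence = 0,
                       expression = list(
                         coamplified = list(sense_rpkm = 20,
                                            antisense_fraction = 0.9,
                                            smallrna_rpkm = 300),
                         background = list(sense_rpkm = 10,
                                           antisense_fraction = 0.1,
                                           smallrna_rpkm = 5)
                       ),
                       rna_total = 2e7, smallrna_total = 1e7,
                       votes_per_scaffold = 6,
                       ancestral_x = "A",
                       autosomal_elements = c("B", "C", "E")) {
  stopifnot(depth_male >= 0, depth_female >= 0, read_len_aa >= 1,
            background_reads >= 0, scaffold_depth >= 0,
            y_divergence >= 0, y_divergence <= 1)
  needed <- c("gene_id", "length_aa", "n_x", "n_y", "n_a", "class")
  if (!all(needed %in% names(genes))) {
    abort(paste0("genes must have columns: ", paste(needed, collapse = ", ")))
  }
  if (any(genes$n_x < 0 | genes$n_y < 0 | genes$n_a < 0)) {
    abort("copy numbers must be >= 0")
  }
  if (any(genes$n_x + genes$n_a == 0 & genes$n_y == 0)) {
    abort("every gene needs at least one genomic copy")
  }
  if (anyDuplicated(genes$gene_id)) abort("gene ids must be unique")
  if (anyDuplicated(scaffolds$scaffold_id)) {
    abort("scaffold ids must be unique")
  }
  structure(list(
    genes = as_tibble(genes), scaffolds = as_tibble(scaffolds),
    depth_male = depth_male, depth_female = depth_female,
    read_len_aa = read_len_aa, background_reads = background_reads,
    scaffold_depth = scaffold_depth,
    scaffold_read_len_bp = scaffold_read_len_bp,
    y_divergence = y_divergence,
    expression = expression, rna_total = rna_total,
    smallrna_total = smallrna_total,
    votes_per_scaffold = votes_per_scaffold,
    ancestral_x = ancestral_x, autosomal_elements = autosomal_elements
  ), class = "sim_config")
}

#' Expected M/F coverage ratio under the copy-number model
#'
#' `(nX + nY + 2 nA) / (2 nX + 2 nA)`; infinite when the gene has no
#' X or autosomal copy (Y-specific).
#'
#' @param n_x,n_y,n_a Copy numbers.
#' @return Expected normalized M/F ratio.
#' @export
expected_mf_ratio <- function(n_x, n_y, n_a = 0) {
  den <- 2 * n_x + 2 * n_a
  ifelse(den > 0, (n_x + n_y + 2 * n_a) / den, Inf)
}

#' Simulate a ground-truth cohort
#'
#' Generates every input the pipeline consumes: peptide reference, gene
#' models placed on scaffolds, male and female translated hit tables,
#' nucleotide hit tables with one exact full-length locus per assembled
#' (X/autosomal) copy, per-scaffold coverage counts, Muller homology labels
#' for element voting, and stranded expression counts — plus the ground
#' truth. Identical seeds give identical output.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; fully determines the output.
#' @return A `sim_cohort` list with elements `peptides`, `gene_models`,
#'   `hits_male`, `hits_female`, `male_total`, `female_total`,
#'   `nucleotide_hits`, `scaffold_coverage`, `scaffold_genes`,
#'   `stranded_counts`, `truth`, `config`, `seed`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(as.integer(seed), simulate_cohort_impl(config, seed))
}

simulate_cohort_impl <- function(config, seed) {
  genes <- config$genes
  scaffolds <- config$scaffolds

  # --- scaffold gene content for Muller voting -------------------------
  votes <- purrr::pmap(
    list(scaffolds$scaffold_id, scaffolds$element,
         seq_len(nrow(scaffolds))),
    function(sc, el, i) {
      if (is.na(el)) return(NULL)
      k <- config$votes_per_scaffold
      lab <- rep(el, k)
      if (i %% 3 == 0 && k >= 2) {
        others <- setdiff(c("A", "B", "C", "D", "E", "F"), el)
        lab[k] <- others[1 + (i %% length(others))]
      }
      tibble(scaffold_id = sc,
             gene_id = sprintf("hom_%s_%02d", sc, seq_len(k)),
             muller_element = lab)
    })
  scaffold_genes <- bind_rows(votes)

  # --- place parent genes on scaffolds of matching linkage -------------
  x_sc <- scaffolds$scaffold_id[scaffolds$linkage_class == "X" &
                                  scaffolds$length_bp >= 8000]
  a_sc <- scaffolds$scaffold_id[scaffolds$linkage_class == "autosome" &
                                  scaffolds$length_bp >= 8000]
  if (length(x_sc) == 0 || length(a_sc) == 0) {
    abort("scaffold layout needs X-linked and autosomal scaffolds >= 8 kb")
  }
  parent_pool <- ifelse(genes$n_x >= 1, "X", "autosome")
  x_idx <- 0L; a_idx <- 0L
  parent_scaffold <- character(nrow(genes))
  slot_on_scaffold <- integer(nrow(genes))
  used <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(genes))) {
    if (parent_pool[i] == "X") {
      x_idx <- x_idx + 1L
      parent_scaffold[i] <- x_sc[1L + (x_idx - 1L) %% length(x_sc)]
    } else {
      a_idx <- a_idx + 1L
      parent_scaffold[i] <- a_sc[1L + (a_idx - 1L) %% length(a_sc)]
    }
    key <- parent_scaffold[i]
    slot <- if (is.null(used[[key]])) 0L else used[[key]]
    used[[key]] <- slot + 1L
    slot_on_scaffold[i] <- slot
  }

  # --- gene models: 1-3 exons per gene, alternating strand -------------
  gm <- purrr::pmap(
    list(genes$gene_id, genes$length_aa, parent_scaffold, slot_on_scaffold,
         seq_len(nrow(genes))),
    function(g, L_aa, sc, slot, i) {
      cds <- 3L * as.integer(L_aa)
      n_ex <- 1L + (i %% 3L)
      cuts <- floor(cds * seq_len(n_ex - 1L) / n_ex)
      sizes <- diff(c(0L, cuts, cds))
      strand <- if (i %% 2L == 0L) "-" else "+"
      base <- 200L + slot * 2600L
      starts <- integer(n_ex); ends <- integer(n_ex)
      pos <- base
      for (k in seq_len(n_ex)) {
        starts[k] <- pos
        ends[k] <- pos + sizes[k] - 1L
        pos <- ends[k] + 120L  # intron
      }
      tibble(gene_id = g, scaffold_id = sc, strand = strand,
             exon_start = starts, exon_end = ends,
             ortholog_id = paste0("Dmel_", g),
             muller_element = scaffolds$element[
               scaffolds$scaffold_id == sc])
    })
  gene_models <- validate_gene_models(bind_rows(gm))

  peptides <- tibble(peptide_id = genes$gene_id,
                     length_aa = as.integer(genes$length_aa))

  # --- translated hit tables -------------------------------------------
  copies_m <- genes$n_x + genes$n_y + 2L * genes$n_a
  copies_f <- 2L * genes$n_x + 2L * genes$n_a
  hits_male <- sim_translated_hits(genes, copies_m, genes$n_y,
                                   config$depth_male, config$read_len_aa,
                                   config$y_divergence, "m")
  hits_female <- sim_translated_hits(genes, copies_f, 0L,
                                     config$depth_female,
                                     config$read_len_aa, 0, "f")
  male_total <- rpois(1, config$background_reads) + nrow(hits_male)
  female_total <- rpois(1, config$background_reads) + nrow(hits_female)

  # --- nucleotide hit tables: one exact locus per assembled copy -------
  nucleotide_hits <- sim_nucleotide_hits(genes, gene_models, scaffolds,
                                         x_sc, a_sc)

  # --- scaffold coverage -----------------------------------------------
  ploidy_m <- c(X = 1, autosome = 2, Y = 1)
  ploidy_f <- c(X = 2, autosome = 2, Y = 0)
  rate <- config$scaffold_depth * scaffolds$length_bp /
    config$scaffold_read_len_bp
  scaffold_coverage <- tibble(
    scaffold_id = scaffolds$scaffold_id,
    length_bp = scaffolds$length_bp,
    male_mapped_reads = rpois(nrow(scaffolds),
                              rate * ploidy_m[scaffolds$linkage_class]),
    female_mapped_reads = rpois(nrow(scaffolds),
                                rate * ploidy_f[scaffolds$linkage_class])
  )

  # --- stranded expression ----------------------------------------------
  stranded_counts <- sim_stranded_counts(genes, gene_models, config)

  truth <- tibble(
    gene_id = genes$gene_id,
    n_x = genes$n_x, n_y = genes$n_y, n_a = genes$n_a,
    class = genes$class,
    parent_scaffold = parent_scaffold,
    parent_linkage = parent_pool,
    expected_mf = expected_mf_ratio(genes$n_x, genes$n_y, genes$n_a)
  )

  structure(list(
    peptides = peptides, gene_models = gene_models,
    hits_male = hits_male, hits_female = hits_female,
    male_total = male_total, female_total = female_total,
    nucleotide_hits = nucleotide_hits,
    scaffold_coverage = scaffold_coverage,
    scaffold_genes = scaffold_genes,
    stranded_counts = stranded_counts,
    truth = truth, config = config, seed = as.integer(seed)
  ), class = "sim_cohort")
}

# Hits are emitted window-aligned: each hit spans one whole 'read_len'-sized
# window and per-window counts are Poisson(depth * copies * n_res /
# min(read_len, n_res)), so window depths under the matching analysis window
# are exactly iid Poisson with mean depth * copies — the depth structure the
# M/F ratio caller assumes.
sim_translated_hits <- function(genes, copies, y_copies, depth, read_len,
                                y_divergence, tag) {
  rows <- purrr::pmap(
    list(genes$gene_id, genes$length_aa, copies, y_copies),
    function(g, L, cp, ny) {
      L <- as.integer(L)
      rl <- as.integer(read_len)
      nw <- ceiling(L / rl)
      w_start <- (seq_len(nw) - 1L) * rl + 1L
      w_end <- pmin(seq_len(nw) * rl, L)
      n_res <- w_end - w_start + 1L
      k <- rpois(nw, depth * cp * n_res / pmin(rl, n_res))
      n <- sum(k)
      if (n == 0) return(NULL)
      win <- rep.int(seq_len(nw), k)
      alen <- n_res[win]
      # which reads come from Y copies (diverged identity, if configured)
      p_y <- if (cp > 0) ny / cp else 0
      from_y <- runif(n) < p_y
      pid <- ifelse(from_y, 100 * (1 - y_divergence), 100)
      tibble(
        read_id = sprintf("rd_%s_%s_%06d", tag, g, seq_len(n)),
        peptide_id = g,
        pct_identity = round(pid, 1),
        align_len = alen,
        mismatches = as.integer(round(alen * (100 - pid) / 100)),
        gap_opens = 0L,
        query_start = 1L, query_end = alen,
        subject_start = w_start[win], subject_end = w_end[win],
        evalue = 1e-30, bitscore = round(2.0 * alen, 1)
      )
    })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(read_id = character(), peptide_id = character(),
                  pct_identity = double(), align_len = integer(),
                  mismatches = integer(), gap_opens = integer(),
                  query_start = integer(), query_end = integer(),
                  subject_start = integer(), subject_end = integer(),
                  evalue = double(), bitscore = double())
  }
  out
}

sim_nucleotide_hits <- function(genes, gene_models, scaffolds, x_sc, a_sc) {
  ex <- arrange(gene_models, .data$gene_id, .data$exon_rank)
  ex_by_gene <- split(ex, ex$gene_id)
  rows <- purrr::pmap(
    list(genes$gene_id, genes$n_x, genes$n_a, seq_len(nrow(genes))),
    function(g, nx, na_copies, i) {
      e <- ex_by_gene[[g]]
      if (is.null(e)) return(NULL)
      exon_len <- e$exon_end - e$exon_start + 1L
      n_copies <- nx + na_copies
      if (n_copies == 0) return(NULL)
      out <- vector("list", n_copies + 1L)
      # copy 1 = the parent at its annotated position
      minus_parent <- e$strand[1] == "-"
      out[[1]] <- tibble(
        query_id = exon_query_id(g, e$exon_rank),
        subject_id = e$scaffold_id,
        pct_identity = 100, align_len = exon_len,
        mismatches = 0L, gap_opens = 0L,
        query_start = 1L, query_end = exon_len,
        subject_start = if (minus_parent) e$exon_end else e$exon_start,
        subject_end = if (minus_parent) e$exon_start else e$exon_end,
        evalue = 1e-180, bitscore = round(1.9 * exon_len, 1)
      )
      # further copies: intron-less, placed high on round-robin scaffolds
      pool_x <- setdiff(x_sc, e$scaffold_id[1])
      if (length(pool_x) == 0) pool_x <- x_sc
      pool_a <- setdiff(a_sc, e$scaffold_id[1])
      if (length(pool_a) == 0) pool_a <- a_sc
      parent_is_x <- nx >= 1L
      copy_specs <- c(rep("X", if (parent_is_x) nx - 1L else nx),
                      rep("autosome",
                          if (parent_is_x) na_copies else na_copies - 1L))
      if (length(copy_specs) > 0) {
        for (j in seq_along(copy_specs)) {
          pool <- if (copy_specs[j] == "X") pool_x else pool_a
          sc <- pool[1L + (i + j) %% length(pool)]
          offset <- 100000L + (i * 7L + j) * 5000L
          minus <- (i + j) %% 2L == 0L
          starts <- offset + cumsum(c(0L, head(exon_len, -1)))
          ends <- starts + exon_len - 1L
          out[[j + 1L]] <- tibble(
            query_id = exon_query_id(g, e$exon_rank),
            subject_id = sc,
            pct_identity = 100, align_len = exon_len,
            mismatches = 0L, gap_opens = 0L,
            query_start = 1L, query_end = exon_len,
            subject_start = if (minus) ends else starts,
            subject_end = if (minus) starts else ends,
            evalue = 1e-180, bitscore = round(1.9 * exon_len, 1)
          )
        }
      }
      # an occasional weak decoy hit, removed by the E-value filter
      if (i %% 5L == 0L) {
        out[[n_copies + 1L]] <- tibble(
          query_id = exon_query_id(g, e$exon_rank[1]),
          subject_id = e$scaffold_id[1],
          pct_identity = 78, align_len = min(60L, exon_len[1]),
          mismatches = 13L, gap_opens = 1L,
          query_start = 1L, query_end = min(60L, exon_len[1]),
          subject_start = 1L,
          subject_end = min(60L, exon_len[1]),
          evalue = 1e-8, bitscore = 40.0
        )
      }
      bind_rows(out)
    })
  out <- bind_rows(rows)
  normalize_hit_strand(out)
}

sim_stranded_counts <- function(genes, gene_models, config) {
  cds <- distinct(gene_models, .data$gene_id, .data$cds_length_bp)
  g <- left_join(genes, cds, by = "gene_id")
  spec_for <- function(cl) {
    if (!is.null(config$expression[[cl]])) config$expression[[cl]] else
      config$expression[["background"]]
  }
  rows <- purrr::pmap(list(g$gene_id, g$class, g$cds_length_bp),
    function(gid, cl, len) {
      sp <- spec_for(cl)
      lam <- function(target_rpkm, total) {
        target_rpkm * len * total / 1e9
      }
      tibble(
        gene_id = gid,
        sense_reads = rpois(1, lam(sp$sense_rpkm, config$rna_total)),
        antisense_reads = rpois(1, lam(sp$sense_rpkm *
                                         sp$antisense_fraction,
                                       config$rna_total)),
        smallrna_reads = rpois(1, lam(sp$smallrna_rpkm,
                                      config$smallrna_total)),
        gene_length_bp = len,
        sense_total = config$rna_total,
        antisense_total = config$rna_total,
        smallrna_total = config$smallrna_total
      )
    })
  bind_rows(rows)
}

#' Write a simulated cohort to a directory
#'
#' Emits every file in the external formats the package reads: peptide
#' FASTA (random amino-acid sequences of the configured lengths; requires
#' Biostrings), headerless 12-column hit TSVs for the male, female and
#' nucleotide searches, gene model TSV, scaffold coverage TSV, Muller
#' homology label TSV, stranded count TSV, library totals TSV, and the
#' ground truth as JSON. Output is byte-deterministic given the cohort.
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_hits_tsv(cohort$hits_male, p("hits_male.tsv"), translated = TRUE)
  write_hits_tsv(cohort$hits_female, p("hits_female.tsv"), translated = TRUE)
  write_hits_tsv(cohort$nucleotide_hits, p("hits_nucleotide.tsv"),
                 translated = FALSE)
  readr::write_tsv(select(cohort$gene_models, "gene_id", "scaffold_id",
                          "strand", "exon_start", "exon_end", "ortholog_id",
                          "muller_element"),
                   p("gene_models.tsv"), progress = FALSE)
  readr::write_tsv(cohort$scaffold_coverage, p("scaffold_coverage.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$scaffold_genes, p("scaffold_genes.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$stranded_counts, p("stranded_counts.tsv"),
                   progress = FALSE)
  readr::write_tsv(tibble(library = c("male", "female"),
                          total_mapped = c(cohort$male_total,
                                           cohort$female_total)),
                   p("library_totals.tsv"), progress = FALSE)
  write_truth(cohort$truth, p("truth.json"))
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    seqs <- withr::with_seed(cohort$seed, vapply(
      cohort$peptides$length_aa,
      function(L) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                               L, replace = TRUE), collapse = ""),
      character(1)))
    aa <- Biostrings::AAStringSet(setNames(seqs,
                                           cohort$peptides$peptide_id))
    Biostrings::writeXStringSet(aa, p("peptides.fasta"))
  }
  invisible(dir)
}

write_hits_tsv <- function(hits, path, translated) {
  if (translated) {
    hits <- rename(hits, query_id = "read_id", subject_id = "peptide_id")
  } else if ("subject_strand" %in% names(hits)) {
    # re-encode strand in coordinate order, the external convention
    minus <- hits$subject_strand == "-"
    s <- ifelse(minus, hits$subject_end, hits$subject_start)
    e <- ifelse(minus, hits$subject_start, hits$subject_end)
    hits$subject_start <- s
    hits$subject_end <- e
    hits$subject_strand <- NULL
    hits$gene_id <- NULL
    hits$exon_rank <- NULL
  }
  hits <- hits[, hit_columns]
  readr::write_tsv(hits, path, col_names = FALSE, progress = FALSE)
}

#' Write ground truth as JSON
#'
#' @param truth Truth tibble from a `sim_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  out$expected_mf <- ifelse(is.infinite(out$expected_mf), "inf",
                            out$expected_mf)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read ground truth written by [write_truth()]
#'
#' Validates the schema and restores infinite expected ratios.
#'
#' @param path Path to a truth JSON file.
#' @return The truth tibble.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("truth file '%s' does not exist", path))
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("gene_id", "n_x", "n_y", "n_a", "class", "parent_scaffold",
              "parent_linkage", "expected_mf")
  if (!is.data.frame(x) || !all(needed %in% names(x))) {
    abort("truth file does not match the expected schema")
  }
  x$expected_mf <- ifelse(x$expected_mf == "inf", Inf,
                          suppressWarnings(as.numeric(x$expected_mf)))
  x$n_x <- as.integer(x$n_x)
  x$n_y <- as.integer(x$n_y)
  x$n_a <- as.integer(x$n_a)
  as_tibble(x)
}
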