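# End-to-end pipeline: simulate (or accept) a cohort, classify scaffold
# linkage, call Y-amplified genes, detect X duplicates, combine into
# co-amplified calls, screen expression, and summarise — with recovery
# metrics against ground truth when available.

#' Run the full co-amplification pipeline on a cohort
#'
#' Chains every stage in dependency order: windowed coverage per sex,
#' library normalization, median M/F ratios; scaffold Muller assignment,
#' coverage classification and neo-X detection; gene parent linkage;
#' Y-amplification calls and the cutoff sweep; X-duplicate detection;
#' co-amplified calls with Y copy-number estimates; and the expression
#' screen. When the cohort carries ground truth, recovery metrics
#' (co-amplification sensitivity and false-positive rate, Spearman
#' correlation of the M/F ratio and of the estimated Y copy number with the
#' true Y copy number, scaffold classification accuracy) are computed.
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()], or a list with
#'   the same elements assembled from real files (`truth` may be absent).
#' @param cutoff M/F ratio cutoff for Y-amplification (default 2.5).
#' @param cutoffs Cutoff sweep grid (default `c(2.5, 5, 7.5, 10)`).
#' @param window_size_aa Coverage window in residues (default 30).
#' @param evalue_cutoff Nucleotide hit E-value threshold (default 1e-20).
#' @param min_fraction Minimum duplicated CDS fraction (default 0.25).
#' @param min_scaffold_bp Minimum scaffold length (default 5000).
#' @param linkage_tolerance log2 band half-width for linkage classes
#'   (default 0.35).
#' @return A `coamp_run` object; see [tidy.coamp_run()] and
#'   [glance.coamp_run()].
#' @export
run_coamp_pipeline <- function(cohort, cutoff = 2.5,
                               cutoffs = c(2.5, 5, 7.5, 10),
                               window_size_aa = 30,
                               evalue_cutoff = 1e-20,
                               min_fraction = 0.25,
                               min_scaffold_bp = 5000,
                               linkage_tolerance = 0.35) {
  needed <- c("peptides", "gene_models", "hits_male", "hits_female",
              "male_total", "female_total", "nucleotide_hits",
              "scaffold_coverage", "scaffold_genes", "stranded_counts")
  missing_el <- setdiff(needed, names(cohort))
  if (length(missing_el) > 0) {
    abort(paste0("cohort is missing elements: ",
                 paste(missing_el, collapse = ", ")))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  cov_m <- stage("coverage", normalize_coverage(
    window_coverage(cohort$hits_male, cohort$peptides, window_size_aa),
    cohort$male_total))
  cov_f <- stage("coverage", normalize_coverage(
    window_coverage(cohort$hits_female, cohort$peptides, window_size_aa),
    cohort$female_total))
  ratios <- stage("mf_ratio", mf_ratio(cov_m, cov_f))

  autos <- cohort$config$autosomal_elements
  anc_x <- cohort$config$ancestral_x
  if (is.null(anc_x)) anc_x <- "A"
  scaff <- stage("linkage", {
    mf <- scaffold_mf(cohort$scaffold_coverage, min_scaffold_bp)
    muller <- assign_muller(cohort$scaffold_genes)
    classify_linkage(
      left_join(mf, select(muller, "scaffold_id", "assigned_element"),
                by = "scaffold_id"),
      autosomal_elements = autos, tolerance = linkage_tolerance
    )
  })
  elements <- stage("linkage", summarize_elements(scaff, anc_x))
  neo_x <- detect_fusion(elements, anc_x)
  linkage <- stage("linkage",
                   gene_parent_linkage(cohort$gene_models, scaff))

  amp <- stage("call_amp", call_y_amplified(ratios, linkage, cutoff))
  sweep <- stage("cutoff_sweep", cutoff_sweep(amp, cutoffs))
  dup <- stage("xdup", call_x_duplicated(
    cohort$nucleotide_hits, cohort$gene_models,
    evalue_cutoff = evalue_cutoff, min_fraction = min_fraction))
  coamp <- stage("coamp", call_coamplified(amp, dup))
  screen <- stage("expr_screen", screen_expression(cohort$stranded_counts))

  recovery <- NULL
  if (!is.null(cohort$truth)) {
    recovery <- recovery_metrics(coamp, scaff, cohort)
  }

  structure(list(
    ratios = ratios, amp = amp, dup = dup, coamp = coamp,
    scaffolds = scaff, elements = elements, neo_x = neo_x,
    linkage = linkage, screen = screen, sweep = sweep,
    recovery = recovery, truth = cohort$truth,
    seed = cohort$seed,
    params = list(cutoff = cutoff, window_size_aa = window_size_aa,
                  evalue_cutoff = evalue_cutoff,
                  min_fraction = min_fraction,
                  min_scaffold_bp = min_scaffold_bp,
                  linkage_tolerance = linkage_tolerance),
    config_hash = rlang::hash(cohort[setdiff(names(cohort),
                                             c("seed"))]),
    version = as.character(utils::packageVersion("coampscan"))
  ), class = "coamp_run")
}

recovery_metrics <- function(coamp, scaff, cohort) {
  truth <- cohort$truth
  j <- inner_join(coamp,
                  select(truth, "gene_id", "n_x", "n_y", "n_a", "class"),
                  by = "gene_id")
  is_true_co <- j$class == "coamplified"
  sens <- if (any(is_true_co)) {
    mean(j$coamplified[is_true_co])
  } else NA_real_
  fpr <- if (any(!is_true_co)) {
    mean(j$coamplified[!is_true_co])
  } else NA_real_
  finite <- is.finite(j$mf_ratio) & j$parent_linkage == "X"
  rho <- if (sum(finite) >= 3) {
    cor(j$mf_ratio[finite], j$n_y[finite], method = "spearman")
  } else NA_real_
  est_ok <- !is.na(j$est_y_copies)
  mae <- if (any(est_ok)) {
    mean(abs(j$est_y_copies[est_ok] - j$n_y[est_ok]))
  } else NA_real_
  sc_truth <- cohort$config$scaffolds
  acc <- NA_real_
  if (!is.null(sc_truth)) {
    sj <- inner_join(scaff,
                     select(sc_truth, "scaffold_id",
                            true_class = "linkage_class"),
                     by = "scaffold_id")
    acc <- mean(sj$linkage_class == sj$true_class)
  }
  list(coamp_sensitivity = sens, coamp_fpr = fpr,
       spearman_mf_vs_ny = rho, y_copy_mae = mae,
       linkage_accuracy = acc)
}

#' @describeIn run_coamp_pipeline Print a short run summary.
#' @param x A `coamp_run`.
#' @param ... Ignored.
#' @export
print.coamp_run <- function(x, ...) {
  g <- glance(x)
  cat("<coamp_run>\n")
  cat(sprintf("  genes: %d | Y-amplified: %d | co-amplified: %d\n",
              g$n_genes, g$n_y_amplified, g$n_coamplified))
  cat(sprintf("  scaffolds classified: %d | neo-X elements: %s\n",
              g$n_scaffolds,
              if (nrow(x$neo_x) > 0) {
                paste(x$neo_x$element, collapse = ",")
              } else "none"))
  cat(sprintf("  expression screen hits: %d\n", g$n_screen_hits))
  if (!is.null(x$recovery)) {
    cat(sprintf(
      "  recovery: sensitivity %.2f | FPR %.3f | Spearman(MF, nY) %.3f\n",
      x$recovery$coamp_sensitivity, x$recovery$coamp_fpr,
      x$recovery$spearman_mf_vs_ny))
  }
  invisible(x)
}

#' Tidy gene-level results of a pipeline run
#'
#' @param x A `coamp_run`.
#' @param ... Ignored.
#' @return The per-gene call table (one row per gene) joining the coverage
#'   ratio, linkage, duplicate and co-amplification columns, plus the
#'   expression screen verdict.
#' @method tidy coamp_run
#' @export
tidy.coamp_run <- function(x, ...) {
  out <- left_join(x$coamp,
                   select(x$screen, "gene_id", "passes_screen"),
                   by = "gene_id")
  out
}

#' One-row summary of a pipeline run
#'
#' @param x A `coamp_run`.
#' @param ... Ignored.
#' @return A one-row tibble of stage counts, neo-X elements, recovery
#'   metrics (NA without ground truth), seed and version.
#' @method glance coamp_run
#' @export
glance.coamp_run <- function(x, ...) {
  rec <- x$recovery
  tibble(
    n_genes = nrow(x$coamp),
    n_y_amplified = sum(x$coamp$y_amplified),
    n_coamplified = sum(x$coamp$coamplified),
    n_x_duplicated = sum(x$coamp$x_duplicated),
    n_scaffolds = nrow(x$scaffolds),
    n_neo_x = nrow(x$neo_x),
    n_screen_hits = sum(x$screen$passes_screen),
    coamp_sensitivity = rec$coamp_sensitivity %||% NA_real_,
    coamp_fpr = rec$coamp_fpr %||% NA_real_,
    spearman_mf_vs_ny = rec$spearman_mf_vs_ny %||% NA_real_,
    y_copy_mae = rec$y_copy_mae %||% NA_real_,
    linkage_accuracy = rec$linkage_accuracy %||% NA_real_,
    seed = x$seed %||% NA_integer_,
    version = x$version
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline run summary as JSON
#'
#' Serializes the [glance.coamp_run()] row, the cutoff sweep and the neo-X
#' element list. Reproducible: identical runs give identical files.
#'
#' @param run A `coamp_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(run, path) {
  g <- as.list(glance(run))
  out <- list(
    summary = g,
    cutoff_sweep = run$sweep,
    neo_x_elements = run$neo_x$element,
    params = run$params,
    config_hash = run$config_hash
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
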