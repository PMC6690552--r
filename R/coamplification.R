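# Co-amplified X/Y gene calls: a gene amplified on the Y (by male/female
# coverage) that also has at least two copies on the X. Includes the
# copy-number inversion of the coverage expectation and the one-sided exact
# enrichment test used for annotation categories.

#' Combine Y-amplification and X-duplication calls
#'
#' A gene is co-amplified when it is Y-amplified (M/F coverage ratio at the
#' cutoff with an X-linked parent) and has at least two copies on the X,
#' operationalized as `x_duplicated = TRUE` for the X-linked parent (the
#' >= 25%-of-CDS duplication rule). Genes present in only one input are
#' reported with a missing-data status and never called. Y copy numbers are
#' estimated by inverting the coverage expectation (see
#' [estimate_y_copies()]) with `n_x_loci` taken from the duplicate call's
#' per-base maximum locus count.
#'
#' @param amp Output of [call_y_amplified()].
#' @param dup Output of [call_x_duplicated()].
#' @return A tibble with `gene_id`, `mf_ratio`, `parent_linkage`,
#'   `y_amplified`, `x_duplicated`, `n_x_loci`, `coamplified`,
#'   `est_y_copies`, `status`.
#' @export
call_coamplified <- function(amp, dup) {
  a <- select(amp, "gene_id", "mf_ratio", "flag", "parent_linkage",
              "y_amplified", "status")
  d <- select(dup, "gene_id", "x_duplicated", "n_loci_max_cov")
  j <- full_join(mutate(a, .in_amp = TRUE), mutate(d, .in_dup = TRUE),
                 by = "gene_id")
  out <- mutate(j,
    status = dplyr::case_when(
      is.na(.data$.in_amp) ~ "missing_coverage_call",
      is.na(.data$.in_dup) ~ "missing_duplicate_call",
      TRUE ~ .data$status
    ),
    y_amplified = dplyr::coalesce(.data$y_amplified, FALSE),
    x_duplicated = dplyr::coalesce(.data$x_duplicated, FALSE),
    n_x_loci = dplyr::coalesce(.data$n_loci_max_cov, 0L),
    coamplified = !is.na(.data$.in_amp) & !is.na(.data$.in_dup) &
      .data$y_amplified & .data$x_duplicated &
      .data$parent_linkage %in% "X"
  )
  estimable <- is.finite(out$mf_ratio) & out$n_x_loci >= 1 &
    out$parent_linkage %in% "X"
  out$est_y_copies <- NA_real_
  out$est_y_copies[estimable] <- estimate_y_copies(
    out$mf_ratio[estimable], out$n_x_loci[estimable])
  select(out, "gene_id", "mf_ratio", "parent_linkage", "y_amplified",
         "x_duplicated", "n_x_loci", "coamplified", "est_y_copies",
         "status")
}

#' Estimate Y copy number from the M/F coverage ratio
#'
#' Inverts the coverage-expectation model: a male carries `nX + nY + 2 nA`
#' copies and a female `2 nX + 2 nA`, so the expected normalized M/F ratio
#' is `(nX + nY + 2 nA) / (2 nX + 2 nA)` and the Y copy number is
#' `ratio * (2 nX + 2 nA) - nX - 2 nA`, floored at zero.
#'
#' @param mf_ratio Finite normalized M/F coverage ratio(s).
#' @param n_x_loci Number of X-linked copies (>= 1).
#' @param n_autosomal_loci Number of autosomal copies (default 0; the
#'   default assumes all non-Y copies are X-linked, matching the
#'   X-linked-parent restriction of the caller).
#' @return Estimated Y copy number(s), non-negative.
#' @examples
#' estimate_y_copies(2.5, 1) # 4 Y copies
#' @export
estimate_y_copies <- function(mf_ratio, n_x_loci, n_autosomal_loci = 0) {
  if (any(!is.finite(mf_ratio))) {
    abort("mf_ratio must be finite; infinite ratios have no X parent to scale by")
  }
  if (any(n_x_loci < 1)) abort("n_x_loci must be >= 1")
  pmax(mf_ratio * (2 * n_x_loci + 2 * n_autosomal_loci) -
         n_x_loci - 2 * n_autosomal_loci, 0)
}

#' One-sided Fisher's exact test (enrichment direction)
#'
#' Upper-tail hypergeometric probability of observing at least `k` annotated
#' genes among `n` candidates, when `K` of `N` background genes carry the
#' annotation.
#'
#' @param k Annotated candidates observed.
#' @param n Number of candidates.
#' @param K Annotated genes in the background.
#' @param N Background size.
#' @return P(X >= k), exact.
#' @export
fisher_one_sided <- function(k, n, K, N) {
  bad <- k < 0 | n < 0 | K < 0 | N < 1 | n > N | K > N | k > n | k > K |
    (n - k) > (N - K)
  if (any(bad)) abort("impossible contingency table")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Annotation-category enrichment among candidate genes
#'
#' Tests whether candidate genes (e.g. co-amplified X/Y genes) are enriched
#' for an annotation category (e.g. testis expression) relative to the
#' background of all annotated genes, with a one-sided Fisher's exact test.
#'
#' @param candidates Character vector of candidate gene ids (or a calls
#'   tibble with `gene_id` and a logical `coamplified` column, in which case
#'   the co-amplified genes are used).
#' @param annotation Tibble with `gene_id` and logical `in_category` (the
#'   background is every gene in `annotation`).
#' @param category Label for the report.
#' @return A one-row tibble: `category`, `k_in`, `n_candidates`,
#'   `K_background`, `N_background`, `p_one_sided`.
#' @export
test_enrichment <- function(candidates, annotation,
                            category = "annotated") {
  if (is.data.frame(candidates)) {
    candidates <- candidates$gene_id[candidates$coamplified %in% TRUE]
  }
  if (!all(c("gene_id", "in_category") %in% names(annotation))) {
    abort("annotation must have gene_id and in_category columns")
  }
  if (anyDuplicated(annotation$gene_id)) {
    abort("annotation gene ids must be unique")
  }
  candidates <- intersect(unique(candidates), annotation$gene_id)
  N <- nrow(annotation)
  K <- sum(annotation$in_category)
  n <- length(candidates)
  k <- sum(annotation$in_category[annotation$gene_id %in% candidates])
  tibble(category = category, k_in = k, n_candidates = n,
         K_background = K, N_background = N,
         p_one_sided = fisher_one_sided(k, n, K, N))
}
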