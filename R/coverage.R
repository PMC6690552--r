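# Windowed read coverage over the peptide reference, library-size
# normalization, the median-based male/female coverage ratio, and the
# Y-amplification caller.
#
# The depth model: a gene with nX X-linked, nY Y-linked and nA autosomal
# copies is sequenced at depth proportional to nX + nY + 2*nA in a male
# (one X, one Y, two of each autosome) and 2*nX + 2*nA in a female, so the
# normalized M/F ratio has expectation (nX + nY + 2*nA) / (2*nX + 2*nA):
# ~1 for autosomal single-copy genes, ~0.5 for X-linked single-copy genes,
# and elevated for Y-amplified genes.

#' Windowed read coverage per peptide
#'
#' Computes mean per-residue read depth in non-overlapping windows (default
#' 30 amino acids) along each peptide, from translated-search hits of genomic
#' reads against the peptide reference. Window depth is the sum over the
#' window's residues of the number of hits covering each residue, divided by
#' the number of residues in the window; a trailing window shorter than
#' `window_size_aa` keeps its true residue count as denominator. Peptides
#' with no hits get all-zero windows.
#'
#' @param hits Tibble of translated hits with columns `peptide_id`,
#'   `subject_start`, `subject_end` (1-based inclusive amino-acid positions).
#' @param peptides Tibble with `peptide_id` and `length_aa`; every peptide in
#'   `hits` must appear here and all hits must lie within the peptide.
#' @param window_size_aa Window width in residues (default 30).
#' @return A tibble with one row per window: `peptide_id`, `window_index`,
#'   `n_residues`, `depth`.
#' @export
window_coverage <- function(hits, peptides, window_size_aa = 30) {
  stopifnot(is.numeric(window_size_aa), window_size_aa >= 1)
  if (anyDuplicated(peptides$peptide_id)) {
    abort("peptide ids must be unique")
  }
  if (any(peptides$length_aa < 1)) abort("peptide length_aa must be >= 1")
  unknown <- setdiff(unique(hits$peptide_id), peptides$peptide_id)
  if (length(unknown) > 0) {
    abort(paste0("hits reference unknown peptides: ",
                 paste(head(unknown, 3), collapse = ", ")))
  }
  len <- setNames(as.integer(peptides$length_aa), peptides$peptide_id)
  if (nrow(hits) > 0) {
    bad <- which(hits$subject_start < 1 |
                   hits$subject_end > len[hits$peptide_id] |
                   hits$subject_start > hits$subject_end)
    if (length(bad) > 0) {
      b <- bad[1]
      abort(sprintf(
        "hit %s:%d-%d outside peptide bounds (length %d)",
        hits$peptide_id[b], hits$subject_start[b], hits$subject_end[b],
        len[hits$peptide_id[b]]
      ))
    }
  }
  by_pep <- split(seq_len(nrow(hits)), factor(hits$peptide_id,
                                              levels = peptides$peptide_id))
  res <- purrr::map2(peptides$peptide_id, peptides$length_aa, function(p, L) {
    L <- as.integer(L)
    idx <- by_pep[[p]]
    cov <- residue_coverage(hits$subject_start[idx], hits$subject_end[idx], L)
    nw <- ceiling(L / window_size_aa)
    win <- ((seq_len(L) - 1L) %/% as.integer(window_size_aa)) + 1L
    n_res <- tabulate(win, nbins = nw)
    depth <- as.numeric(rowsum(cov, win, reorder = TRUE)) / n_res
    tibble(peptide_id = p, window_index = seq_len(nw),
           n_residues = n_res, depth = depth)
  })
  bind_rows(res)
}

# Per-residue hit coverage by difference array; s, e 1-based inclusive.
residue_coverage <- function(s, e, L) {
  if (length(s) == 0) return(numeric(L))
  delta <- tabulate(s, nbins = L) - tabulate(e + 1L, nbins = L + 1L)[1:L]
  cumsum(delta)
}

#' Normalize windowed coverage by library size
#'
#' Divides each window depth by the library's total mapped reads, reported
#' per million mapped reads for readability (a pure rescaling that cancels
#' in the M/F ratio).
#'
#' @param cov Window coverage tibble from [window_coverage()].
#' @param library_total Total mapped reads of the library (> 0).
#' @return `cov` with a `depth_norm` column (depth per million mapped reads).
#' @export
normalize_coverage <- function(cov, library_total) {
  if (!is.numeric(library_total) || length(library_total) != 1 ||
      is.na(library_total) || library_total <= 0) {
    abort("library_total must be a single positive number")
  }
  mutate(cov, depth_norm = .data$depth / library_total * 1e6)
}

#' Median-based male/female coverage ratio per gene
#'
#' For each peptide, takes the median of the normalized male window depths
#' and of the normalized female window depths, and forms their ratio. The
#' two coverage profiles must be on the same window grid. A gene whose
#' female median is zero but male median positive gets an infinite ratio and
#' the flag `"female_zero"` (putatively Y-specific); a gene with both
#' medians zero is flagged `"no_coverage"` and excluded from calling.
#'
#' @param male_cov,female_cov Normalized window coverage tibbles (from
#'   [window_coverage()] then [normalize_coverage()]) for the male and
#'   female libraries.
#' @return A tibble with `gene_id`, `male_median_norm`, `female_median_norm`,
#'   `mf_ratio` and `flag` (`"ok"`, `"female_zero"` or `"no_coverage"`).
#' @export
mf_ratio <- function(male_cov, female_cov) {
  for (cc in c("peptide_id", "window_index", "depth_norm")) {
    if (!cc %in% names(male_cov) || !cc %in% names(female_cov)) {
      abort("coverage tibbles must be normalized (see normalize_coverage)")
    }
  }
  m <- summarise(group_by(male_cov, .data$peptide_id),
                 n_windows = n(), male_median_norm = median(.data$depth_norm),
                 .groups = "drop")
  f <- summarise(group_by(female_cov, .data$peptide_id),
                 n_windows = n(),
                 female_median_norm = median(.data$depth_norm),
                 .groups = "drop")
  j <- full_join(m, f, by = "peptide_id", suffix = c("_m", "_f"))
  if (anyNA(j$n_windows_m) || anyNA(j$n_windows_f) ||
      any(j$n_windows_m != j$n_windows_f)) {
    abort("male and female coverage profiles are on different window grids")
  }
  out <- mutate(j,
    mf_ratio = dplyr::case_when(
      .data$female_median_norm > 0 ~
        .data$male_median_norm / .data$female_median_norm,
      .data$male_median_norm > 0 ~ Inf,
      TRUE ~ NA_real_
    ),
    flag = dplyr::case_when(
      .data$female_median_norm > 0 ~ "ok",
      .data$male_median_norm > 0 ~ "female_zero",
      TRUE ~ "no_coverage"
    )
  )
  select(rename(out, gene_id = "peptide_id"),
         "gene_id", "male_median_norm", "female_median_norm",
         "mf_ratio", "flag")
}

#' Call Y-amplified genes from M/F coverage ratios
#'
#' A gene is called Y-amplified when its normalized M/F coverage ratio is at
#' least `cutoff` (default 2.5) and its parent copy is X-linked. Genes with
#' no coverage are never called; genes with infinite ratio (zero female
#' coverage) are reported as putatively Y-specific but not called, since a
#' Y-amplified gene requires an X-linked (hence female-covered) parent;
#' genes whose parent linkage is not known are reported as
#' `"unknown_linkage"` and not called.
#'
#' @param ratios Tibble from [mf_ratio()].
#' @param linkage Tibble with `gene_id` and `parent_linkage`
#'   (`"X"`, `"autosome"`, `"Y"` or `"unknown"`).
#' @param cutoff Minimum M/F ratio for a call (default 2.5).
#' @return `ratios` with `parent_linkage`, `y_amplified`, `cutoff_used` and
#'   a `status` column explaining uncalled genes.
#' @export
call_y_amplified <- function(ratios, linkage, cutoff = 2.5) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff > 0)
  if (!all(c("gene_id", "parent_linkage") %in% names(linkage))) {
    abort("linkage must have gene_id and parent_linkage columns")
  }
  out <- left_join(ratios, select(linkage, "gene_id", "parent_linkage"),
                   by = "gene_id")
  out <- mutate(out,
    parent_linkage = dplyr::coalesce(.data$parent_linkage, "unknown"),
    y_amplified = .data$flag == "ok" &
      is.finite(.data$mf_ratio) & .data$mf_ratio >= cutoff &
      .data$parent_linkage == "X",
    cutoff_used = cutoff,
    status = dplyr::case_when(
      .data$flag == "no_coverage" ~ "no_coverage",
      .data$flag == "female_zero" ~ "y_specific_candidate",
      !(.data$parent_linkage %in% c("X", "autosome")) ~ "unknown_linkage",
      .data$y_amplified ~ "y_amplified",
      TRUE ~ "not_amplified"
    )
  )
  out
}

#' Caller behaviour across a sweep of M/F ratio cutoffs
#'
#' Re-applies the Y-amplification rule at each cutoff and reports the number
#' of genes called, as in sensitivity analyses of the ratio threshold.
#' The count is non-increasing in the cutoff by construction.
#'
#' @param calls Output of [call_y_amplified()] (or [mf_ratio()] joined with
#'   parent linkage).
#' @param cutoffs Numeric vector of distinct cutoffs (e.g. `c(2.5, 5, 7.5, 10)`).
#' @return A tibble with `cutoff` and `n_called`, sorted by cutoff.
#' @export
cutoff_sweep <- function(calls, cutoffs) {
  if (length(cutoffs) == 0) abort("cutoffs must be non-empty")
  if (anyDuplicated(cutoffs)) abort("cutoffs must be distinct")
  if (!all(c("mf_ratio", "flag", "parent_linkage") %in% names(calls))) {
    abort("calls must carry mf_ratio, flag and parent_linkage")
  }
  eligible <- calls$flag == "ok" & is.finite(calls$mf_ratio) &
    calls$parent_linkage == "X"
  tibble(
    cutoff = sort(cutoffs),
    n_called = vapply(sort(cutoffs),
                      function(ct) sum(eligible & calls$mf_ratio >= ct),
                      integer(1))
  )
}
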