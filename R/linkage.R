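# Scaffold-level sex-linkage inference: Muller-element assignment by gene
# content, per-scaffold normalized M/F coverage, classification into
# X / autosome / Y from the log2 ratio relative to an autosomal baseline,
# and detection of X-autosome fusions (neo-X elements).

#' Assign scaffolds to Muller elements by gene content
#'
#' Each scaffold is assigned the Muller element (A-F) holding a strict
#' majority (> half) of its genes' homology labels; ties or scaffolds with
#' no labelled genes are left unassigned.
#'
#' @param gene_elements Tibble with `scaffold_id`, `gene_id`,
#'   `muller_element` (NA labels are dropped).
#' @return A tibble with `scaffold_id`, `n_genes`, `assigned_element`
#'   (NA when unassigned) and a list-column `element_votes` of named counts.
#' @export
assign_muller <- function(gene_elements) {
  needed <- c("scaffold_id", "gene_id", "muller_element")
  if (!all(needed %in% names(gene_elements))) {
    abort(paste0("gene_elements must have columns: ",
                 paste(needed, collapse = ", ")))
  }
  ge <- filter(gene_elements, !is.na(.data$muller_element))
  votes <- count(ge, .data$scaffold_id, .data$muller_element, name = "votes")
  out <- summarise(group_by(votes, .data$scaffold_id),
    n_genes = sum(.data$votes),
    assigned_element = {
      top <- max(.data$votes)
      winner <- .data$muller_element[.data$votes == top]
      if (length(winner) == 1 && top > sum(.data$votes) / 2) {
        winner
      } else {
        NA_character_
      }
    },
    element_votes = list(setNames(.data$votes, .data$muller_element)),
    .groups = "drop"
  )
  # scaffolds present in the input but with no labelled genes
  all_sc <- distinct(gene_elements, .data$scaffold_id)
  out <- left_join(all_sc, out, by = "scaffold_id")
  out$n_genes[is.na(out$n_genes)] <- 0L
  out$element_votes <- purrr::map(out$element_votes,
                                  ~ if (is.null(.x)) integer(0) else .x)
  out
}

#' Per-scaffold normalized male/female coverage ratio
#'
#' Computes the library-size-normalized M/F coverage ratio
#' `(male_reads / male_total) / (female_reads / female_total)` per scaffold.
#' Scaffolds shorter than `min_length_bp` (default 5 kb) are excluded.
#' Scaffolds with zero female but positive male reads get an infinite ratio
#' (Y-contig signature). Read counts are expected to be derived from
#' alignments with mapping quality >= 20 (an upstream contract).
#'
#' @param coverage Tibble of scaffold coverage records (`scaffold_id`,
#'   `length_bp`, `male_mapped_reads`, `female_mapped_reads`).
#' @param min_length_bp Minimum scaffold length retained (default 5000).
#' @param male_total,female_total Library totals; default to the column sums
#'   over all input scaffolds (before the length filter).
#' @return A tibble with `scaffold_id`, `length_bp`, `mf_norm`, `log2_mf`.
#' @export
scaffold_mf <- function(coverage, min_length_bp = 5000,
                        male_total = NULL, female_total = NULL) {
  if (is.null(male_total)) male_total <- sum(coverage$male_mapped_reads)
  if (is.null(female_total)) female_total <- sum(coverage$female_mapped_reads)
  if (male_total <= 0 || female_total <= 0) {
    abort("library totals must be positive")
  }
  kept <- filter(coverage, .data$length_bp >= min_length_bp)
  out <- mutate(kept,
    mf_norm = dplyr::case_when(
      .data$female_mapped_reads > 0 ~
        (.data$male_mapped_reads / male_total) /
        (.data$female_mapped_reads / female_total),
      .data$male_mapped_reads > 0 ~ Inf,
      TRUE ~ NA_real_
    ),
    log2_mf = log2(.data$mf_norm)
  )
  select(out, "scaffold_id", "length_bp", "mf_norm", "log2_mf")
}

#' Classify scaffolds as X-linked, autosomal or Y-linked
#'
#' Classifies each scaffold from the offset of its log2 M/F ratio relative
#' to an autosomal baseline: an X-linked scaffold sits one doubling below
#' the autosomal level (half male coverage), a Y scaffold has (near-)zero
#' female coverage or at least one doubling above. With
#' `delta = log2_mf - baseline`: X when `delta` is within `tolerance` of -1,
#' autosome when within `tolerance` of 0, Y when `delta >= 1` or the ratio
#' is infinite, otherwise ambiguous.
#'
#' The baseline is the median `log2_mf` of scaffolds assigned to
#' user-declared autosomal elements; when no declaration is given, the mode
#' of the finite scaffold `log2_mf` distribution (kernel density argmax) is
#' used, which is robust to a neo-X element as long as most scaffolds are
#' autosomal.
#'
#' @param scaffolds Tibble joining [scaffold_mf()] and [assign_muller()]
#'   output: columns `scaffold_id`, `length_bp`, `mf_norm`, `log2_mf`, and
#'   `assigned_element`.
#' @param autosomal_elements Optional character vector of elements known to
#'   be autosomal, used for the baseline.
#' @param tolerance Half-width of the log2 acceptance bands (default 0.35).
#' @return `scaffolds` with `delta_log2` and `linkage_class`
#'   (`"X"`, `"autosome"`, `"Y"`, `"ambiguous"`); the baseline is attached
#'   as the `"autosomal_baseline_log2"` attribute.
#' @export
classify_linkage <- function(scaffolds, autosomal_elements = NULL,
                             tolerance = 0.35) {
  stopifnot(is.numeric(tolerance), tolerance > 0)
  needed <- c("scaffold_id", "mf_norm", "log2_mf", "assigned_element")
  if (!all(needed %in% names(scaffolds))) {
    abort(paste0("scaffolds must have columns: ",
                 paste(needed, collapse = ", ")))
  }
  finite <- scaffolds$log2_mf[is.finite(scaffolds$log2_mf)]
  if (!is.null(autosomal_elements)) {
    base_vals <- scaffolds$log2_mf[
      scaffolds$assigned_element %in% autosomal_elements &
        is.finite(scaffolds$log2_mf)
    ]
    if (length(base_vals) == 0) {
      abort(paste0(
        "no finite coverage ratios on the declared autosomal elements; ",
        "check `autosomal_elements`"
      ))
    }
    baseline <- median(base_vals)
  } else {
    if (length(finite) == 0) {
      abort(paste0(
        "no finite scaffold coverage ratios to derive an autosomal ",
        "baseline from; supply `autosomal_elements` explicitly"
      ))
    }
    if (length(finite) == 1) {
      baseline <- finite
    } else {
      d <- density(finite)
      baseline <- d$x[which.max(d$y)]
    }
  }
  out <- mutate(scaffolds,
    delta_log2 = .data$log2_mf - baseline,
    linkage_class = dplyr::case_when(
      is.na(.data$mf_norm) ~ "ambiguous",
      is.infinite(.data$mf_norm) | .data$delta_log2 >= 1 ~ "Y",
      abs(.data$delta_log2 + 1) <= tolerance ~ "X",
      abs(.data$delta_log2) <= tolerance ~ "autosome",
      TRUE ~ "ambiguous"
    )
  )
  attr(out, "autosomal_baseline_log2") <- baseline
  out
}

#' Per-element linkage report
#'
#' Summarises classified scaffolds per Muller element: the element's
#' linkage class is the length-weighted majority of its scaffolds' classes,
#' and ancestrally autosomal elements classified X are flagged as neo-X
#' (X-autosome fusion).
#'
#' @param scaffolds Output of [classify_linkage()] (with `length_bp`).
#' @param ancestral_x Character vector of elements forming the ancestral X
#'   (default `"A"`, the Muller element that is X-linked across Drosophila).
#' @return A tibble with `element`, `n_scaffolds`, `median_log2_mf`,
#'   `linkage_class`, `is_neo`.
#' @export
summarize_elements <- function(scaffolds, ancestral_x = "A") {
  cl <- filter(scaffolds, !is.na(.data$assigned_element))
  out <- summarise(group_by(cl, element = .data$assigned_element),
    n_scaffolds = n(),
    median_log2_mf = median(.data$log2_mf),
    linkage_class = {
      w <- tapply(.data$length_bp, .data$linkage_class, sum)
      names(w)[which.max(w)]
    },
    .groups = "drop"
  )
  mutate(out,
         is_neo = .data$linkage_class == "X" &
           !(.data$element %in% ancestral_x))
}

#' Detect neo-X elements (X-autosome fusions)
#'
#' Returns the ancestrally autosomal Muller elements whose scaffolds are
#' X-linked by coverage — the signature of a chromosome arm recently fused
#' to the sex chromosomes.
#'
#' @param element_report Output of [summarize_elements()].
#' @param ancestral_x Elements of the ancestral X (excluded by definition).
#' @return A tibble of neo-X elements (possibly empty).
#' @export
detect_fusion <- function(element_report, ancestral_x = "A") {
  filter(element_report,
         .data$linkage_class == "X" & !(.data$element %in% ancestral_x))
}

#' Gene-level parent linkage from scaffold classes
#'
#' Maps each gene's scaffold to its linkage class to obtain the parent-copy
#' linkage used by the Y-amplification caller.
#'
#' @param genes Gene model tibble (`gene_id`, `scaffold_id`).
#' @param scaffolds Output of [classify_linkage()].
#' @return A tibble with `gene_id`, `scaffold_id`, `parent_linkage`
#'   (`"X"`, `"autosome"`, `"Y"` or `"unknown"`).
#' @export
gene_parent_linkage <- function(genes, scaffolds) {
  g <- distinct(genes, .data$gene_id, .data$scaffold_id)
  g <- left_join(g, select(scaffolds, "scaffold_id", "linkage_class"),
                 by = "scaffold_id")
  mutate(g, parent_linkage = dplyr::case_when(
    .data$linkage_class %in% c("X", "autosome", "Y") ~ .data$linkage_class,
    TRUE ~ "unknown"
  ))[, c("gene_id", "scaffold_id", "parent_linkage")]
}
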