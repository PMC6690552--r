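# Testis expression screen: RPKM from stranded RNA-seq and small-RNA
# counts, and the three-filter screen for genes that are expressed in
# testis, antisense-transcribed, and produce small RNAs — the signature of
# an endo-siRNA-generating (putative genomic-conflict) locus.

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count * 1e9 / (gene_length_bp * library_total)`.
#'
#' @param count Read count(s), >= 0.
#' @param gene_length_bp Gene model length in bp (>= 1).
#' @param library_total Total mapped reads of the library (>= 1).
#' @return RPKM value(s).
#' @examples
#' rpkm(1000, 1000, 1e6) # 1000
#' @export
rpkm <- function(count, gene_length_bp, library_total) {
  if (any(gene_length_bp < 1)) abort("gene_length_bp must be >= 1")
  if (any(library_total < 1)) abort("library_total must be >= 1")
  if (any(count < 0)) abort("counts must be >= 0")
  count * 1e9 / (gene_length_bp * library_total)
}

#' Screen for antisense-transcribed, small-RNA-producing testis genes
#'
#' Applies three filters to per-gene stranded counts: expressed in testis
#' (sense RPKM >= `sense_min`, default 2), antisense transcription at least
#' `antisense_frac_min` of sense expression (default 0.75, compared on
#' RPKM; ties pass), and small-RNA production (small-RNA RPKM >=
#' `smallrna_min`, default 100, normalized by the small-RNA library's own
#' total). Counts are expected to come from alignments with mapping quality
#' >= 20 (upstream contract).
#'
#' @param counts Stranded count tibble (`gene_id`, `sense_reads`,
#'   `antisense_reads`, `smallrna_reads`, `gene_length_bp`, `sense_total`,
#'   `antisense_total`, `smallrna_total`).
#' @param sense_min Minimum sense RPKM (default 2).
#' @param antisense_frac_min Minimum antisense/sense RPKM ratio
#'   (default 0.75).
#' @param smallrna_min Minimum small-RNA RPKM (default 100).
#' @return A tibble with per-gene RPKMs, `antisense_fraction` (NA when
#'   sense is zero) and `passes_screen`.
#' @export
screen_expression <- function(counts, sense_min = 2,
                              antisense_frac_min = 0.75,
                              smallrna_min = 100) {
  needed <- c("gene_id", "sense_reads", "antisense_reads", "smallrna_reads",
              "gene_length_bp", "sense_total", "antisense_total",
              "smallrna_total")
  if (!all(needed %in% names(counts))) {
    abort(paste0("counts must have columns: ",
                 paste(setdiff(needed, names(counts)), collapse = ", ")))
  }
  out <- mutate(counts,
    sense_rpkm = rpkm(.data$sense_reads, .data$gene_length_bp,
                      .data$sense_total),
    antisense_rpkm = rpkm(.data$antisense_reads, .data$gene_length_bp,
                          .data$antisense_total),
    smallrna_rpkm = rpkm(.data$smallrna_reads, .data$gene_length_bp,
                         .data$smallrna_total),
    antisense_fraction = dplyr::if_else(
      .data$sense_rpkm > 0, .data$antisense_rpkm / .data$sense_rpkm,
      NA_real_
    ),
    passes_screen = .data$sense_rpkm >= sense_min &
      .data$antisense_rpkm >= antisense_frac_min * .data$sense_rpkm &
      .data$sense_rpkm > 0 &
      .data$smallrna_rpkm >= smallrna_min
  )
  select(out, "gene_id", "sense_rpkm", "antisense_rpkm", "smallrna_rpkm",
         "antisense_fraction", "passes_screen")
}

#' Per-copy sense/antisense shares within gene families
#'
#' For each gene family, computes each member's share of the family's total
#' sense RPKM and of its total antisense RPKM (shares sum to 1 per family
#' per strand). Used to ask which copy of a co-amplified family produces
#' the antisense transcripts. A family with zero total on a strand has
#' undefined shares on that strand and is flagged.
#'
#' @param expression Output of [screen_expression()] (or any tibble with
#'   `gene_id`, `sense_rpkm`, `antisense_rpkm`).
#' @param families Tibble with `gene_id` and `family_id`.
#' @return A tibble with `family_id`, `gene_id`, `sense_share`,
#'   `antisense_share` (NA where undefined) and `flag`.
#' @export
strand_partition <- function(expression, families) {
  if (!all(c("gene_id", "family_id") %in% names(families))) {
    abort("families must have gene_id and family_id columns")
  }
  j <- inner_join(families, expression, by = "gene_id")
  j <- group_by(j, .data$family_id)
  j <- mutate(j,
    sense_share = if (sum(.data$sense_rpkm) > 0) {
      .data$sense_rpkm / sum(.data$sense_rpkm)
    } else {
      NA_real_
    },
    antisense_share = if (sum(.data$antisense_rpkm) > 0) {
      .data$antisense_rpkm / sum(.data$antisense_rpkm)
    } else {
      NA_real_
    },
    flag = dplyr::case_when(
      sum(.data$sense_rpkm) == 0 & sum(.data$antisense_rpkm) == 0 ~
        "both_strands_zero",
      sum(.data$sense_rpkm) == 0 ~ "sense_zero",
      sum(.data$antisense_rpkm) == 0 ~ "antisense_zero",
      TRUE ~ "ok"
    )
  )
  select(ungroup(j), "family_id", "gene_id", "sense_share",
         "antisense_share", "flag")
}
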