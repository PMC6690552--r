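# X-linked duplicate detection: filter nucleotide hits of CDS exons against
# the female assembly, resolve them into distinct genomic loci, and compute
# the fraction of the parent coding sequence aligned to more than one
# location (the >= 25%-of-CDS rule).
#
# Query ids follow the convention "<gene_id>:exon<rank>" where rank is the
# exon's order along the coding sequence (strand-aware); query coordinates
# are 1-based along that exon in transcript orientation.

#' Build the exon query id used in nucleotide hit tables
#'
#' @param gene_id Gene identifier.
#' @param exon_rank Exon rank along the CDS (1-based).
#' @return Character vector of ids of the form `"<gene_id>:exon<rank>"`.
#' @export
exon_query_id <- function(gene_id, exon_rank) {
  paste0(gene_id, ":exon", exon_rank)
}

parse_exon_query <- function(query_id) {
  m <- stringr::str_match(query_id, "^(.*):exon(\\d+)$")
  if (anyNA(m[, 1])) {
    bad <- query_id[is.na(m[, 1])][1]
    abort(sprintf(
      "query id '%s' does not follow the '<gene>:exon<rank>' convention", bad))
  }
  tibble(gene_id = m[, 2], exon_rank = as.integer(m[, 3]))
}

#' Filter nucleotide hits by E-value
#'
#' Retains only hits at or below a stringent E-value cutoff (default 1e-20),
#' the first step of duplicate detection.
#'
#' @param hits Tibble of nucleotide hits with an `evalue` column.
#' @param evalue_cutoff Maximum E-value retained (default `1e-20`).
#' @return The filtered tibble.
#' @export
filter_nucleotide_hits <- function(hits, evalue_cutoff = 1e-20) {
  stopifnot(is.numeric(evalue_cutoff), evalue_cutoff >= 0)
  filter(hits, .data$evalue <= evalue_cutoff)
}

#' Resolve nucleotide hits into distinct genomic loci
#'
#' Groups a gene's subject intervals into loci: intervals on the same
#' scaffold whose reciprocal overlap exceeds `merge_overlap` (default 0.5 of
#' BOTH intervals) are merged into one locus, transitively. Remaining
#' intervals are distinct loci. Output order is deterministic (scaffold,
#' then start).
#'
#' @param hits Tibble of strand-normalized, E-filtered nucleotide hits with
#'   columns `gene_id`, `subject_id`, `subject_start`, `subject_end`.
#' @param merge_overlap Reciprocal-overlap fraction above which two
#'   intervals are considered the same locus (default 0.5).
#' @return A tibble of loci: `gene_id`, `locus_id` (per gene, 1..n),
#'   `scaffold_id`, `start`, `end`, `n_hits`; plus a `.locus` assignment
#'   column joined back onto the hits in the `hits` attribute is not kept —
#'   use [assign_hit_loci()] when per-hit locus ids are needed.
#' @export
resolve_loci <- function(hits, merge_overlap = 0.5) {
  assigned <- assign_hit_loci(hits, merge_overlap)
  if (nrow(assigned) == 0) {
    return(tibble(gene_id = character(), locus_id = integer(),
                  scaffold_id = character(), start = double(),
                  end = double(), n_hits = integer()))
  }
  loci <- summarise(group_by(assigned, .data$gene_id, .data$locus_id),
                    scaffold_id = first(.data$subject_id),
                    start = min(.data$subject_start),
                    end = max(.data$subject_end),
                    n_hits = n(), .groups = "drop")
  arrange(loci, .data$gene_id, .data$scaffold_id, .data$start)
}

#' Assign a locus id to every nucleotide hit
#'
#' Single-linkage clustering of each gene's subject intervals: two intervals
#' on the same scaffold belong to the same locus when their reciprocal
#' overlap (overlap length divided by each interval's length) exceeds
#' `merge_overlap` for both. Locus ids are numbered per gene in
#' (scaffold, start) order.
#'
#' @inheritParams resolve_loci
#' @return `hits` with an integer `locus_id` column.
#' @export
assign_hit_loci <- function(hits, merge_overlap = 0.5) {
  stopifnot(is.numeric(merge_overlap), merge_overlap >= 0, merge_overlap <= 1)
  needed <- c("gene_id", "subject_id", "subject_start", "subject_end")
  if (!all(needed %in% names(hits))) {
    abort(paste0("hits must have columns: ", paste(needed, collapse = ", ")))
  }
  if (nrow(hits) == 0) {
    hits$locus_id <- integer()
    return(hits)
  }
  if (any(hits$subject_start > hits$subject_end)) {
    abort("subject coordinates must be strand-normalized (start <= end)")
  }
  hits <- arrange(hits, .data$gene_id, .data$subject_id, .data$subject_start,
                  .data$subject_end)
  split_idx <- split(seq_len(nrow(hits)), hits$gene_id)
  hits$locus_id <- NA_integer_
  for (idx in split_idx) {
    s <- hits$subject_start[idx]
    e <- hits$subject_end[idx]
    sc <- hits$subject_id[idx]
    k <- length(idx)
    # union-find over pairwise reciprocal overlaps
    parent <- seq_len(k)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    if (k > 1) {
      for (i in seq_len(k - 1)) {
        for (j in (i + 1):k) {
          if (sc[i] != sc[j]) next
          ov <- min(e[i], e[j]) - max(s[i], s[j]) + 1
          if (ov <= 0) next
          if (ov / (e[i] - s[i] + 1) > merge_overlap &&
              ov / (e[j] - s[j] + 1) > merge_overlap) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[ri] <- rj
          }
        }
      }
    }
    roots <- vapply(seq_len(k), find, integer(1))
    # number clusters by first (scaffold, start) appearance: idx is sorted
    hits$locus_id[idx] <- as.integer(factor(roots, levels = unique(roots)))
  }
  hits
}

#' Map exon-local query coordinates onto the concatenated CDS
#'
#' Converts each hit's query interval (1-based along one exon, in transcript
#' orientation) to coordinates on the gene's concatenated coding sequence,
#' using the gene models' strand-aware exon ranks.
#'
#' @param hits Nucleotide hits whose `query_id` follows the
#'   `"<gene>:exon<rank>"` convention.
#' @param genes Gene model tibble from [read_gene_models()] /
#'   [validate_gene_models()].
#' @return `hits` with `gene_id`, `exon_rank`, `cds_start`, `cds_end` added.
#' @export
map_query_to_cds <- function(hits, genes) {
  if (nrow(hits) == 0) {
    hits$gene_id <- character()
    hits$exon_rank <- integer()
    hits$cds_start <- double()
    hits$cds_end <- double()
    return(hits)
  }
  q <- parse_exon_query(hits$query_id)
  hits$gene_id <- q$gene_id
  hits$exon_rank <- q$exon_rank
  ex <- mutate(
    arrange(genes, .data$gene_id, .data$exon_rank),
    exon_len = .data$exon_end - .data$exon_start + 1L
  )
  ex <- mutate(group_by(ex, .data$gene_id),
               cds_offset = cumsum(.data$exon_len) - .data$exon_len)
  ex <- ungroup(ex)
  hits <- left_join(hits,
                    select(ex, "gene_id", "exon_rank", "exon_len",
                           "cds_offset"),
                    by = c("gene_id", "exon_rank"))
  if (anyNA(hits$cds_offset)) {
    bad <- hits$query_id[is.na(hits$cds_offset)][1]
    abort(sprintf("query '%s' references an unknown gene or exon", bad))
  }
  bad <- which(hits$query_start < 1 | hits$query_end > hits$exon_len |
                 hits$query_start > hits$query_end)
  if (length(bad) > 0) {
    abort(sprintf("query interval of '%s' lies outside its exon (length %d)",
                  hits$query_id[bad[1]], hits$exon_len[bad[1]]))
  }
  hits$cds_start <- hits$cds_offset + hits$query_start
  hits$cds_end <- hits$cds_offset + hits$query_end
  hits$exon_len <- NULL
  hits$cds_offset <- NULL
  hits
}

#' Per-gene CDS duplication fraction and X-duplication call
#'
#' For each CDS base, counts the distinct genomic loci whose hits cover it;
#' the duplication fraction is the fraction of CDS bases covered by at least
#' two loci. A gene is called duplicated when that fraction reaches
#' `min_fraction` (default 0.25). The gene's own (parent) locus counts as
#' one of the locations; set `exclude_parent_locus = TRUE` to instead
#' require the fraction to be covered by at least one non-parent locus (the
#' parent locus being the one overlapping the gene's annotated position).
#'
#' Also reported: `n_loci`, the number of resolved loci (note that each exon
#' of a multi-exon parent contributes its own subject interval, so this
#' overcounts "locations" for multi-exon genes), and `n_loci_max_cov`, the
#' maximum per-base distinct-locus count — for full-length copies this
#' equals the genomic copy number.
#'
#' @param hits Nucleotide hit tibble (strand-normalized; will be E-filtered,
#'   locus-resolved and CDS-mapped internally).
#' @param genes Gene model tibble covering every gene in `hits`.
#' @param evalue_cutoff E-value threshold (default 1e-20).
#' @param min_fraction Minimum duplicated fraction of the CDS (default 0.25).
#' @param merge_overlap Reciprocal-overlap merge threshold for loci
#'   (default 0.5).
#' @param exclude_parent_locus Require duplicated coverage to come from
#'   non-parent loci (default `FALSE`).
#' @return A tibble with one row per gene in `genes`: `gene_id`,
#'   `cds_length_bp`, `n_loci`, `n_loci_max_cov`, `dup_fraction`,
#'   `x_duplicated`, `evalue_cutoff`, `min_fraction`.
#' @export
call_x_duplicated <- function(hits, genes, evalue_cutoff = 1e-20,
                              min_fraction = 0.25, merge_overlap = 0.5,
                              exclude_parent_locus = FALSE) {
  stopifnot(is.numeric(min_fraction), min_fraction >= 0, min_fraction <= 1)
  genes <- validate_gene_models(genes)
  hits <- normalize_hit_strand(hits)
  hits <- filter_nucleotide_hits(hits, evalue_cutoff)
  hits <- map_query_to_cds(hits, genes)
  hits <- assign_hit_loci(hits, merge_overlap)

  gene_tbl <- distinct(genes, .data$gene_id, .data$scaffold_id,
                       .data$cds_length_bp)
  gene_span <- summarise(group_by(genes, .data$gene_id),
                         gene_start = min(.data$exon_start),
                         gene_end = max(.data$exon_end), .groups = "drop")
  gene_tbl <- left_join(gene_tbl, gene_span, by = "gene_id")

  per_gene <- purrr::pmap(gene_tbl, function(gene_id, scaffold_id,
                                             cds_length_bp, gene_start,
                                             gene_end) {
    h <- hits[hits$gene_id == gene_id, , drop = FALSE]
    L <- as.integer(cds_length_bp)
    if (nrow(h) == 0) {
      return(tibble(gene_id = gene_id, cds_length_bp = L, n_loci = 0L,
                    n_loci_max_cov = 0L, dup_fraction = 0))
    }
    locus_ids <- sort(unique(h$locus_id))
    # identify the parent locus: any locus overlapping the annotated span
    parent_loci <- integer(0)
    if (isTRUE(exclude_parent_locus)) {
      ov <- h$subject_id == scaffold_id &
        h$subject_start <= gene_end & h$subject_end >= gene_start
      parent_loci <- unique(h$locus_id[ov])
    }
    cov_count <- integer(L)
    for (lid in locus_ids) {
      sel <- h$locus_id == lid
      bit <- logical(L)
      ss <- pmax(1L, as.integer(h$cds_start[sel]))
      ee <- pmin(L, as.integer(h$cds_end[sel]))
      for (i in seq_along(ss)) if (ss[i] <= ee[i]) bit[ss[i]:ee[i]] <- TRUE
      cov_count <- cov_count + as.integer(bit)
    }
    if (isTRUE(exclude_parent_locus) && length(parent_loci) > 0) {
      nonparent <- integer(L)
      for (lid in setdiff(locus_ids, parent_loci)) {
        sel <- h$locus_id == lid
        bit <- logical(L)
        ss <- pmax(1L, as.integer(h$cds_start[sel]))
        ee <- pmin(L, as.integer(h$cds_end[sel]))
        for (i in seq_along(ss)) if (ss[i] <= ee[i]) bit[ss[i]:ee[i]] <- TRUE
        nonparent <- nonparent + as.integer(bit)
      }
      dup_frac <- sum(nonparent >= 1L) / L
    } else {
      dup_frac <- sum(cov_count >= 2L) / L
    }
    tibble(gene_id = gene_id, cds_length_bp = L,
           n_loci = length(locus_ids),
           n_loci_max_cov = as.integer(max(cov_count)),
           dup_fraction = dup_frac)
  })
  out <- bind_rows(per_gene)
  mutate(out,
         x_duplicated = .data$dup_fraction >= min_fraction,
         evalue_cutoff = evalue_cutoff,
         min_fraction = min_fraction)
}
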