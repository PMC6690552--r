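# Readers/writers for the external tabular formats and the coordinate
# conventions shared by every caller. All coordinates, internal and external,
# are 1-based inclusive (the R/Bioconductor convention); minus-strand
# nucleotide hits (subject_start > subject_end) are normalized on read to
# (min, max) plus an explicit strand flag.

#' Column names of the 12-column tabular alignment format
#'
#' The conventional tab-separated alignment report (BLAST/DIAMOND "format 6"):
#' query, subject, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, E-value, bit score.
#'
#' @keywords internal
hit_columns <- c(
  "query_id", "subject_id", "pct_identity", "align_len", "mismatches",
  "gap_opens", "query_start", "query_end", "subject_start", "subject_end",
  "evalue", "bitscore"
)

#' Read a 12-column tabular alignment hit file
#'
#' Parses the conventional 12-column tab-separated alignment output used both
#' for translated searches of genomic reads against a peptide reference and
#' for nucleotide searches of CDS exons against a genome assembly. Every row
#' must parse; a malformed row (wrong column count, non-numeric coordinate)
#' raises an error naming the offending line.
#'
#' @param path Path to a headerless tab-separated file with the conventional
#'   12 columns (query, subject, \%identity, length, mismatches, gap opens,
#'   qstart, qend, sstart, send, evalue, bitscore).
#' @param kind `"translated"` for read-vs-peptide hits (subject coordinates in
#'   amino acids; returned with `read_id`/`peptide_id` names) or
#'   `"nucleotide"` for exon-vs-assembly hits (subject coordinates in bp;
#'   minus-strand hits normalized, with a `subject_strand` column added).
#' @return A tibble of hits, one row per alignment.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines("r1\tpep1\t95.0\t30\t0\t0\t1\t90\t11\t40\t1e-12\t60.1", tf)
#' read_alignment_hits(tf, kind = "translated")
#' @export
read_alignment_hits <- function(path, kind = c("translated", "nucleotide")) {
  kind <- rlang::arg_match(kind)
  spec <- readr::cols(
    query_id = readr::col_character(),
    subject_id = readr::col_character(),
    pct_identity = readr::col_double(),
    align_len = readr::col_integer(),
    mismatches = readr::col_integer(),
    gap_opens = readr::col_integer(),
    query_start = readr::col_integer(),
    query_end = readr::col_integer(),
    subject_start = readr::col_integer(),
    subject_end = readr::col_integer(),
    evalue = readr::col_double(),
    bitscore = readr::col_double()
  )
  hits <- suppressWarnings(
    readr::read_tsv(path, col_names = hit_columns, col_types = spec,
                    na = character(), progress = FALSE)
  )
  if (nrow(hits) > 0 && ncol(hits) != length(hit_columns)) {
    abort(sprintf(
      "malformed alignment row at line 1 of '%s': expected %d columns, got %d",
      path, length(hit_columns), ncol(hits)
    ))
  }
  probs <- readr::problems(hits)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "malformed alignment row at line %d of '%s': expected %s, got '%s'",
      probs$row[1], path, probs$expected[1], probs$actual[1]
    ))
  }
  if (nrow(hits) == 0) {
    hits <- hits[0, ]
  }
  if (any(hits$evalue < 0)) {
    abort(sprintf("negative E-value at line %d of '%s'",
                  which(hits$evalue < 0)[1], path))
  }
  if (kind == "translated") {
    bad <- which(hits$subject_start > hits$subject_end |
                   hits$subject_start < 1)
    if (length(bad) > 0) {
      abort(sprintf(
        "translated hit at line %d of '%s' has invalid subject interval %d-%d",
        bad[1], path, hits$subject_start[bad[1]], hits$subject_end[bad[1]]
      ))
    }
    hits <- rename(hits, read_id = "query_id", peptide_id = "subject_id")
  } else {
    hits <- normalize_hit_strand(hits)
  }
  hits
}

#' Normalize minus-strand subject coordinates of nucleotide hits
#'
#' Nucleotide alignment reports encode minus-strand hits as
#' `subject_start > subject_end`. This swaps such coordinates to
#' `(min, max)` and records the orientation in a `subject_strand` column
#' (`"+"`/`"-"`). Idempotent: rows already carrying a strand column and
#' ordered coordinates are returned unchanged.
#'
#' @param hits A tibble of nucleotide hits with `subject_start`/`subject_end`.
#' @return The tibble with ordered subject coordinates and `subject_strand`.
#' @export
normalize_hit_strand <- function(hits) {
  if (!all(c("subject_start", "subject_end") %in% names(hits))) {
    abort("hits must have subject_start and subject_end columns")
  }
  minus <- hits$subject_start > hits$subject_end
  if (!"subject_strand" %in% names(hits)) {
    hits$subject_strand <- ifelse(minus, "-", "+")
  } else {
    hits$subject_strand[minus] <- "-"
  }
  lo <- pmin(hits$subject_start, hits$subject_end)
  hi <- pmax(hits$subject_start, hits$subject_end)
  hits$subject_start <- lo
  hits$subject_end <- hi
  hits
}

#' Read a GFF-like gene model table
#'
#' Reads a tab-separated gene model file with one row per exon and a header:
#' `gene_id`, `scaffold_id`, `strand`, `exon_start`, `exon_end`,
#' `ortholog_id`, `muller_element` (the last two may be `NA`). Intervals are
#' 1-based inclusive. Exons are sorted by genomic start within each gene and
#' checked for overlap; the CDS length of each gene is recomputed as the sum
#' of its exon lengths.
#'
#' @param path Path to the gene model TSV.
#' @return A tibble with one row per exon, plus per-gene `exon_rank` (order
#'   along the coding sequence: genomic order on `+`, reversed on `-`) and
#'   `cds_length_bp`.
#' @export
read_gene_models <- function(path) {
  spec <- readr::cols(
    gene_id = readr::col_character(),
    scaffold_id = readr::col_character(),
    strand = readr::col_character(),
    exon_start = readr::col_integer(),
    exon_end = readr::col_integer(),
    ortholog_id = readr::col_character(),
    muller_element = readr::col_character()
  )
  genes <- suppressWarnings(
    readr::read_tsv(path, col_types = spec, progress = FALSE)
  )
  probs <- readr::problems(genes)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed gene model row at line %d of '%s'",
                  probs$row[1], path))
  }
  if (nrow(genes) == 0) return(validate_gene_models(genes))
  validate_gene_models(genes)
}

#' Validate and canonicalize a gene model tibble
#'
#' Sorts exons, rejects overlapping exons within a gene, assigns CDS exon
#' ranks (strand-aware) and recomputes `cds_length_bp`.
#'
#' @param genes Tibble with columns `gene_id`, `scaffold_id`, `strand`,
#'   `exon_start`, `exon_end` and optionally `ortholog_id`, `muller_element`.
#' @return The canonicalized tibble with `exon_rank` and `cds_length_bp`.
#' @export
validate_gene_models <- function(genes) {
  needed <- c("gene_id", "scaffold_id", "strand", "exon_start", "exon_end")
  missing_cols <- setdiff(needed, names(genes))
  if (length(missing_cols) > 0) {
    abort(paste0("gene models missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"ortholog_id" %in% names(genes)) genes$ortholog_id <- NA_character_
  if (!"muller_element" %in% names(genes)) {
    genes$muller_element <- NA_character_
  }
  if (nrow(genes) == 0) {
    genes$exon_rank <- integer()
    genes$cds_length_bp <- integer()
    return(as_tibble(genes))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("gene model strand must be '+' or '-'")
  }
  if (any(genes$exon_start < 1 | genes$exon_end < genes$exon_start)) {
    bad <- which(genes$exon_start < 1 | genes$exon_end < genes$exon_start)[1]
    abort(sprintf("invalid exon interval %d-%d for gene '%s'",
                  genes$exon_start[bad], genes$exon_end[bad],
                  genes$gene_id[bad]))
  }
  genes <- arrange(genes, .data$gene_id, .data$exon_start)
  genes <- group_by(genes, .data$gene_id)
  genes <- mutate(genes,
    .overlap = .data$exon_start <= lag(.data$exon_end, default = 0L),
    cds_length_bp = sum(.data$exon_end - .data$exon_start + 1L),
    exon_rank = if (first(.data$strand) == "+") {
      row_number()
    } else {
      n() - row_number() + 1L
    }
  )
  genes <- ungroup(genes)
  if (any(genes$.overlap)) {
    bad <- genes$gene_id[genes$.overlap][1]
    abort(sprintf("overlapping exons in gene '%s'", bad))
  }
  genes$.overlap <- NULL
  as_tibble(genes)
}

#' Read a per-scaffold coverage table
#'
#' Tab-separated with a header: `scaffold_id`, `length_bp`,
#' `male_mapped_reads`, `female_mapped_reads`. Read counts are expected to
#' come from alignments with mapping quality of at least 20 (enforced
#' upstream, at the aligner step).
#'
#' @param path Path to the coverage TSV.
#' @return A tibble of scaffold coverage records.
#' @export
read_scaffold_coverage <- function(path) {
  spec <- readr::cols(
    scaffold_id = readr::col_character(),
    length_bp = readr::col_double(),
    male_mapped_reads = readr::col_double(),
    female_mapped_reads = readr::col_double()
  )
  cov <- suppressWarnings(
    readr::read_tsv(path, col_types = spec, progress = FALSE)
  )
  probs <- readr::problems(cov)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed scaffold coverage row at line %d of '%s'",
                  probs$row[1], path))
  }
  if (nrow(cov) > 0 &&
      any(cov$length_bp < 1 | cov$male_mapped_reads < 0 |
            cov$female_mapped_reads < 0)) {
    abort("scaffold coverage: counts must be >= 0 and length_bp >= 1")
  }
  cov
}

#' Read a stranded count table
#'
#' Tab-separated with a header: `gene_id`, `sense_reads`, `antisense_reads`,
#' `smallrna_reads`, `gene_length_bp`, `sense_total`, `antisense_total`,
#' `smallrna_total`. The totals are the total mapped reads of the stranded
#' RNA library (sense and antisense strands of the same library) and of the
#' separate small-RNA library.
#'
#' @param path Path to the stranded count TSV.
#' @return A tibble of stranded count records.
#' @export
read_stranded_counts <- function(path) {
  spec <- readr::cols(
    gene_id = readr::col_character(),
    sense_reads = readr::col_double(),
    antisense_reads = readr::col_double(),
    smallrna_reads = readr::col_double(),
    gene_length_bp = readr::col_double(),
    sense_total = readr::col_double(),
    antisense_total = readr::col_double(),
    smallrna_total = readr::col_double()
  )
  x <- suppressWarnings(
    readr::read_tsv(path, col_types = spec, progress = FALSE)
  )
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed stranded count row at line %d of '%s'",
                  probs$row[1], path))
  }
  x
}

#' Write a result table as TSV
#'
#' Writes any caller output tibble as a header-ed TSV with a deterministic
#' column order (the tibble's order). Non-finite numerics are serialized as
#' the literal tokens `inf`, `-inf` and `nan` so the table round-trips
#' losslessly through [read_result_tsv()].
#'
#' @param x A tibble of validated records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  out <- mutate(x, across(dplyr::where(is.numeric), fmt_num_token))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

fmt_num_token <- function(v) {
  s <- vapply(v, function(z) {
    if (is.na(z) && !is.nan(z)) return(NA_character_)
    if (is.nan(z)) return("nan")
    if (is.infinite(z)) return(if (z > 0) "inf" else "-inf")
    format(z, digits = 17, scientific = NA, trim = TRUE)
  }, character(1))
  s
}

#' Read a result table written by [write_result_tsv()]
#'
#' Restores column types: columns whose values are all numeric (or the
#' tokens `inf`/`-inf`/`nan`) become doubles, all-`TRUE`/`FALSE` columns
#' become logical, integral doubles stay doubles, everything else stays
#' character.
#'
#' @param path Path to a TSV written by [write_result_tsv()].
#' @return A tibble.
#' @export
read_result_tsv <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE, na = "NA")
  as_tibble(lapply(x, parse_token_column))
}

parse_token_column <- function(v) {
  nonmiss <- v[!is.na(v)]
  if (length(nonmiss) > 0 && all(nonmiss %in% c("TRUE", "FALSE"))) {
    return(as.logical(v))
  }
  mapped <- v
  mapped[v == "inf"] <- "Inf"
  mapped[v == "-inf"] <- "-Inf"
  mapped[v == "nan"] <- "NaN"
  num <- suppressWarnings(as.numeric(mapped))
  if (length(nonmiss) > 0 && !anyNA(num[!is.na(v)])) {
    return(num)
  }
  v
}

#' Read peptide lengths from a FASTA reference
#'
#' Reads an amino-acid FASTA file (the longest-isoform peptide set the
#' translated search ran against) and returns ids and lengths. Requires the
#' Biostrings package.
#'
#' @param path Path to a FASTA file of peptide sequences.
#' @return A tibble with `peptide_id` and `length_aa`.
#' @export
read_peptides <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA requires the Biostrings package")
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    abort("duplicate peptide ids in FASTA reference")
  }
  tibble(peptide_id = ids, length_aa = Biostrings::width(aa))
}
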