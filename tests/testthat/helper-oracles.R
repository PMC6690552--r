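# Independent brute-force oracles used by the property and acceptance
# tests. These deliberately share no code with the package internals.

# Mean per-residue depth per non-overlapping window, by naive accumulation.
oracle_window_depths <- function(starts, ends, length_aa, window) {
  depth <- numeric(length_aa)
  for (i in seq_along(starts)) {
    for (pos in starts[i]:ends[i]) depth[pos] <- depth[pos] + 1
  }
  nw <- ceiling(length_aa / window)
  out <- numeric(nw)
  for (w in seq_len(nw)) {
    lo <- (w - 1) * window + 1
    hi <- min(w * window, length_aa)
    out[w] <- mean(depth[lo:hi])
  }
  out
}

# Fraction of CDS bases covered by >= 2 distinct loci, by per-locus bitmap.
oracle_dup_fraction <- function(cds_len, locus_ids, cds_starts, cds_ends) {
  counts <- integer(cds_len)
  for (lid in unique(locus_ids)) {
    bit <- rep(FALSE, cds_len)
    sel <- which(locus_ids == lid)
    for (i in sel) {
      bit[cds_starts[i]:cds_ends[i]] <- TRUE
    }
    counts <- counts + bit
  }
  sum(counts >= 2) / cds_len
}

# Upper-tail hypergeometric probability by direct enumeration with choose().
oracle_hyper_tail <- function(k, n, K, N) {
  i <- k:min(n, K)
  if (length(i) == 0 || k > min(n, K)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Single-linkage clustering of intervals by reciprocal overlap, brute force
# (transitive closure over the full adjacency matrix).
oracle_locus_clusters <- function(scaffold, s, e, merge_overlap = 0.5) {
  k <- length(s)
  adj <- diag(k) > 0
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (scaffold[i] != scaffold[j]) next
      ov <- min(e[i], e[j]) - max(s[i], s[j]) + 1
      if (ov > 0 &&
          ov / (e[i] - s[i] + 1) > merge_overlap &&
          ov / (e[j] - s[j] + 1) > merge_overlap) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  reach <- adj
  for (r in seq_len(k)) reach <- (reach %*% adj > 0) | reach
  comp <- integer(k)
  nxt <- 0L
  for (i in seq_len(k)) {
    if (comp[i] == 0L) {
      nxt <- nxt + 1L
      comp[reach[i, ]] <- nxt
    }
  }
  comp
}

# Random translated hit set over one peptide.
random_hit_set <- function(length_aa, n_hits) {
  s <- sample.int(length_aa, n_hits, replace = TRUE)
  e <- pmin(length_aa, s + sample.int(40, n_hits, replace = TRUE) - 1L)
  tibble::tibble(
    peptide_id = "pep", subject_start = s, subject_end = e
  )
}

# Minimal cohort config for fast simulation-based tests.
tiny_config <- function(genes, ...) {
  sim_config(genes = genes, scaffolds = demo_scaffold_table(), ...)
}
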