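# Independent oracles and fixture builders shared across test files.
# Every oracle here is implemented without touching the package's own code
# paths for the operation it checks.

# Build a repertoire from amino-acid sequences and counts; nucleotide
# sequences are synthesised as distinct placeholders unless given.
make_rep <- function(aa, counts, productive = TRUE, nt = NULL,
                     patient_id = "P1", timepoint = "C1D1",
                     sample_id = paste0(patient_id, "_", timepoint),
                     total_reads = NULL) {
  n <- length(aa)
  if (is.null(nt)) nt <- sprintf("NT%04d", seq_len(n))
  repertoire(
    data.frame(nt_cdr3 = nt, aa_cdr3 = aa, read_count = counts,
               productive = rep_len(productive, n)),
    sample_id = sample_id, patient_id = patient_id, timepoint = timepoint,
    total_reads = total_reads)
}

random_aa_strings <- function(n, min_len = 3, max_len = 12,
                              alphabet = c("A", "C", "D", "S", "T")) {
  vapply(seq_len(n), function(i) {
    paste0(sample(alphabet, sample(min_len:max_len, 1), replace = TRUE),
           collapse = "")
  }, character(1))
}

# Brute-force TCF: enumerate all unordered clone pairs, mark clones with at
# least one exact amino-acid match, sum their frequencies.
oracle_tcf <- function(aa, freq) {
  n <- length(aa)
  shared <- rep(FALSE, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (aa[i] == aa[j]) shared[i] <- shared[j] <- TRUE
      }
    }
  }
  sum(freq[shared])
}

# Union-find single-linkage closure over all pairs at distance <= max_dist,
# using utils::adist as the distance routine.
oracle_groups <- function(seqs, max_dist = 1) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (n >= 2) {
    d <- utils::adist(seqs)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (d[i, j] <= max_dist) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots, levels = unique(roots)))
}

# Floyd-Warshall all-pairs shortest paths on an adjacency matrix; returns
# the maximum finite off-diagonal distance (0 for edgeless graphs).
oracle_diameter <- function(adj) {
  n <- nrow(adj)
  if (n == 0) return(0L)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  finite <- d[is.finite(d)]
  as.integer(max(finite))
}

# Random undirected graph as an igraph object plus its adjacency matrix.
random_graph <- function(n, p_edge = 0.1) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  on <- up[stats::runif(length(up)) < p_edge]
  adj[on] <- 1L
  adj <- adj + t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  list(graph = g, adj = adj)
}
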