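# Amino-acid CDR3 similarity networks: Levenshtein distances, convergent
# groups (single-linkage clusters at distance <= 1), and graph diameter.

#' Levenshtein (edit) distance between strings
#'
#' Unit-cost insertions, deletions, and substitutions. Vectorised over both
#' arguments with the usual recycling of length-1 inputs.
#'
#' @param a,b Character vectors.
#' @return Integer vector of distances.
#' @export
#' @examples
#' levenshtein("kitten", "sitting")  # 3
#' levenshtein("CASSL", "CASTL")     # 1
levenshtein <- function(a, b) {
  cpp_levenshtein(as.character(a), as.character(b))
}

#' Sparse pairwise distance pairs under a threshold
#'
#' Computes, for a set of sequences, exactly the unordered pairs whose
#' Levenshtein distance is at most `max_relevant` — equivalent to
#' thresholding the dense distance matrix, but using length bucketing
#' (pairs whose length difference exceeds the threshold are skipped) and a
#' banded dynamic programme with early abandoning.
#'
#' @param sequences Character vector.
#' @param max_relevant Maximum distance of interest (default 1).
#' @return A tibble with columns `i`, `j` (1-based indices, `i < j`) and
#'   `dist`.
#' @export
pairwise_distance_matrix <- function(sequences, max_relevant = 1L) {
  stopifnot(length(sequences) >= 1L, max_relevant >= 0L)
  out <- cpp_bounded_pairs(as.character(sequences), as.integer(max_relevant))
  tibble::as_tibble(out)
}

#' Convergent groups: single-linkage clusters at a distance threshold
#'
#' Two sequences belong to the same convergent group iff they are connected
#' by a chain of sequence pairs each within Levenshtein distance `max_dist`
#' (transitive closure; with the default threshold of 1 this allows a
#' maximum of one amino-acid difference per link). Singleton groups are
#' allowed.
#'
#' @param sequences Character vector.
#' @param max_dist Distance threshold per link (default 1).
#' @return Integer vector of cluster memberships (1-based, in order of first
#'   appearance).
#' @export
convergent_groups <- function(sequences, max_dist = 1L) {
  stopifnot(max_dist >= 0L)
  n <- length(sequences)
  if (!n) return(integer())
  pairs <- pairwise_distance_matrix(sequences, max_dist)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(pairs)) {
    g <- igraph::add_edges(g, rbind(pairs$i, pairs$j))
  }
  comp <- igraph::components(g)$membership
  # relabel in order of first appearance for stable output
  as.integer(factor(comp, levels = unique(comp)))
}

#' Build a per-patient convergence network
#'
#' One node per unique (amino-acid CDR3, timepoint) pair among productive
#' clones, pooling both timepoints of the course into a single graph; the
#' node frequency is the summed frequency of the nucleotide clones mapping
#' to that amino-acid sequence at that timepoint. An undirected edge joins
#' every node pair within Levenshtein distance `max_dist`; distance-0 edges
#' can only join the same sequence observed at both timepoints.
#'
#' @param course A `patient_course` from [pair_timepoints()], or a single
#'   [repertoire()] object.
#' @param max_dist Edge distance threshold (default 1).
#' @return A `convergence_graph`: a list with `patient_id`, `nodes` (tibble
#'   `aa_cdr3`, `timepoint`, `frequency`, `component`), `edges` (tibble
#'   `i`, `j`, `dist`), `graph` (the underlying igraph object),
#'   `n_components`, and `diameter` (in edges).
#' @export
build_network <- function(course, max_dist = 1L) {
  if (inherits(course, "tcr_repertoire")) {
    reps <- list(course)
    patient_id <- course$patient_id
  } else {
    stopifnot(inherits(course, "patient_course"))
    reps <- Filter(Negate(is.null), list(course$baseline, course$post))
    patient_id <- course$patient_id
  }

  nodes <- dplyr::bind_rows(lapply(reps, function(r) {
    rec <- r$records[r$records$productive, , drop = FALSE]
    rec <- rec[!is.na(rec$aa_cdr3) & nzchar(rec$aa_cdr3), , drop = FALSE]
    if (!nrow(rec)) {
      return(tibble::tibble(aa_cdr3 = character(), timepoint = character(),
                            frequency = double()))
    }
    out <- dplyr::summarise(dplyr::group_by(rec, .data$aa_cdr3),
                            frequency = sum(.data$frequency),
                            .groups = "drop")
    out$timepoint <- r$timepoint
    out[, c("aa_cdr3", "timepoint", "frequency")]
  }))

  n <- nrow(nodes)
  if (!n) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(patient_id = patient_id, nodes = nodes,
                          edges = tibble::tibble(i = integer(), j = integer(),
                                                 dist = integer()),
                          graph = g, n_components = 0L, diameter = 0L),
                     class = "convergence_graph"))
  }

  edges <- pairwise_distance_matrix(nodes$aa_cdr3, max_dist)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$aa_cdr3 <- nodes$aa_cdr3
  igraph::V(g)$timepoint <- nodes$timepoint
  if (nrow(edges)) g <- igraph::add_edges(g, rbind(edges$i, edges$j))
  comp <- igraph::components(g)
  nodes$component <- as.integer(comp$membership)

  structure(list(patient_id = patient_id, nodes = nodes, edges = edges,
                 graph = g, n_components = comp$no,
                 diameter = network_diameter(g)),
            class = "convergence_graph")
}

#' @export
print.convergence_graph <- function(x, ...) {
  cat("<convergence_graph> patient", x$patient_id, "\n")
  cat(sprintf("  %d nodes, %d edges, %d components, diameter %d\n",
              nrow(x$nodes), nrow(x$edges), x$n_components, x$diameter))
  invisible(x)
}

#' Network diameter (longest shortest path)
#'
#' Breadth-first search from every node; the diameter is the largest finite
#' shortest-path length over all connected node pairs, i.e. the maximum over
#' connected components. Unreachable pairs never contribute. Edgeless or
#' empty graphs have diameter 0.
#'
#' @param graph A `convergence_graph` or an igraph object.
#' @param units `"edges"` (default, the longest shortest path counted in
#'   edges) or `"vertices"` (the number of vertices on that path, i.e.
#'   edges + 1 on a graph with at least one node).
#' @return Non-negative integer.
#' @export
network_diameter <- function(graph, units = c("edges", "vertices")) {
  units <- match.arg(units)
  g <- if (inherits(graph, "convergence_graph")) graph$graph else graph
  stopifnot(igraph::is_igraph(g))
  nv <- igraph::vcount(g)
  if (nv == 0L) return(0L)
  d <- as.integer(igraph::diameter(g, directed = FALSE, unconnected = TRUE))
  if (units == "vertices") d + 1L else d
}

#' Split patients at the cohort median network diameter
#'
#' Labels each patient `"high"` when the diameter strictly exceeds the
#' cohort median and `"low"` otherwise (a diameter equal to the median falls
#' in the low group). An even-sized cohort uses the midpoint of the two
#' central order statistics as the median.
#'
#' @param diameters Numeric vector of per-patient diameters.
#' @return A list with `median` and `labels` (character vector,
#'   `"high"`/`"low"`).
#' @export
dichotomize_by_median_diameter <- function(diameters) {
  stopifnot(length(diameters) >= 2L)
  m <- stats::median(diameters)
  labels <- ifelse(diameters > m, "high", "low")
  if (all(labels == "low")) {
    warning("all diameters fall at or below the median; ",
            "every patient is labelled 'low'", call. = FALSE)
  }
  list(median = m, labels = labels)
}

#' Per-patient network summary table
#'
#' @param graphs A list of `convergence_graph` objects.
#' @param units Diameter units, passed to [network_diameter()].
#' @return A tibble: `patient_id`, `n_nodes`, `n_edges`, `n_components`,
#'   `diameter`, `diameter_group` (high/low by the cohort median split).
#' @export
network_summary <- function(graphs, units = c("edges", "vertices")) {
  units <- match.arg(units)
  out <- dplyr::bind_rows(lapply(graphs, function(g) {
    tibble::tibble(patient_id = g$patient_id,
                   n_nodes = nrow(g$nodes), n_edges = nrow(g$edges),
                   n_components = g$n_components,
                   diameter = network_diameter(g, units))
  }))
  if (nrow(out) >= 2L) {
    split <- dichotomize_by_median_diameter(out$diameter)
    out$diameter_group <- split$labels
  } else {
    out$diameter_group <- rep(NA_character_, nrow(out))
  }
  out
}

#' Write a network edge list for external visualisation
#'
#' Plain-text TSV with one row per edge: the two node labels
#' (`aa_cdr3@timepoint`) and their distance.
#'
#' @param graph A `convergence_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "convergence_graph"))
  lab <- paste0(graph$nodes$aa_cdr3, "@", graph$nodes$timepoint)
  out <- tibble::tibble(node_a = lab[graph$edges$i],
                        node_b = lab[graph$edges$j],
                        distance = graph$edges$dist)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
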