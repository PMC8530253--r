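# Per-clinician sociometrics computed from first principles:
# eigenvector centrality (power iteration, binary or weighted adjacency),
# betweenness centrality (Brandes' algorithm over unweighted shortest
# paths) and eccentricity (per-node BFS). The shortest-path kernels live
# in src/centrality.cpp; all three measures are component-local on
# disconnected graphs.

# 1-based endpoint indices of the edge list against the node table.
edge_index <- function(network) {
  ids <- network$nodes$clinician_id
  list(ids = ids, n = length(ids),
       ei = match(network$edges$from, ids),
       ej = match(network$edges$to, ids),
       w = as.numeric(network$edges$weight))
}

#' Connected-component membership
#'
#' @param network a `collab_network`.
#' @return Integer vector of component ids (numbered in order of first
#'   appearance), named by clinician id.
#' @export
component_ids <- function(network) {
  g <- edge_index(network)
  if (g$n == 0L) return(stats::setNames(integer(), character()))
  stats::setNames(cpp_components(g$n, g$ei - 1L, g$ej - 1L), g$ids)
}

#' Eigenvector centrality
#'
#' The influence score of each clinician: proportional to the sum of the
#' scores of its neighbours, i.e. the leading eigenvector of the (optionally
#' weighted) adjacency matrix. High scores mark hubs of information sharing
#' and dissemination. Computed by power iteration independently on every
#' connected component and max-normalised to 1 within each component, so
#' that no component's scores are zeroed out merely for not holding the
#' global dominant eigenvalue. Isolated nodes score 0.
#'
#' The default is the binary adjacency, matching the convention of the
#' graph packages this analysis is calibrated against; on strongly
#' pod-modular staffing graphs the weighted variant localises on the
#' single heaviest sub-team and zeroes everyone else, which makes
#' specialty medians degenerate. `weighted = TRUE` uses patient-day tie
#' weights instead.
#'
#' Iteration runs on A + I: the spectral shift removes the sign oscillation
#' that pure power iteration exhibits on bipartite components while leaving
#' the leading eigenvector unchanged.
#'
#' @param network a `collab_network`.
#' @param weighted use patient-day tie weights instead of the binary
#'   adjacency (default FALSE).
#' @param tol convergence tolerance: max-norm difference between successive
#'   normalised iterates.
#' @param max_iter iteration cap; exceeding it is an error naming the
#'   component.
#' @return Numeric scores in [0, 1] named by clinician id.
#' @export
eigenvector_centrality <- function(network, weighted = FALSE, tol = 1e-10,
                                   max_iter = 10000L) {
  stopifnot(tol > 0, max_iter >= 1L)
  g <- edge_index(network)
  comp <- unname(component_ids(network))
  scores <- numeric(g$n)
  w <- if (weighted) g$w else rep(1, length(g$ei))

  for (c_id in unique(comp)) {
    members <- which(comp == c_id)
    if (length(members) == 1L) next  # isolated node scores 0
    sel <- g$ei %in% members         # both endpoints share a component
    A <- matrix(0, length(members), length(members))
    li <- match(g$ei[sel], members); lj <- match(g$ej[sel], members)
    A[cbind(li, lj)] <- w[sel]
    A[cbind(lj, li)] <- w[sel]
    diag(A) <- diag(A) + 1  # spectral shift
    x <- rep(1, length(members))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      x_new <- as.vector(A %*% x)
      x_new <- x_new / max(x_new)
      if (max(abs(x_new - x)) < tol) { x <- x_new; converged <- TRUE; break }
      x <- x_new
    }
    if (!converged) {
      stop("eigenvector centrality did not converge on component ", c_id,
           " (", length(members), " nodes) after ", max_iter, " iterations")
    }
    scores[members] <- x
  }
  stats::setNames(scores, g$ids)
}

#' Betweenness centrality
#'
#' The share of all-pairs shortest paths passing through each clinician,
#' computed with Brandes' dependency accumulation over unweighted
#' (hop-count) shortest paths, with fractional counting when several
#' shortest paths tie. Scores are normalised by (n-1)(n-2)/2 with n the
#' size of the node's own connected component, so they lie in [0, 1];
#' nodes in components of size <= 2 score 0. High betweenness marks
#' clinicians bridging otherwise-distant parts of the care team. Tie
#' weights are similarities, not path costs, so path finding is
#' hop-based.
#'
#' @param network a `collab_network`.
#' @return Numeric scores in [0, 1] named by clinician id.
#' @export
betweenness_centrality <- function(network) {
  g <- edge_index(network)
  if (g$n == 0L) return(stats::setNames(numeric(), character()))
  cb <- cpp_betweenness_raw(g$n, g$ei - 1L, g$ej - 1L)
  comp <- unname(component_ids(network))
  for (c_id in unique(comp)) {
    members <- which(comp == c_id)
    nc <- length(members)
    cb[members] <- if (nc > 2L) cb[members] / ((nc - 1) * (nc - 2) / 2) else 0
  }
  stats::setNames(cb, g$ids)
}

#' Eccentricity
#'
#' Each clinician's maximum hop distance to any other clinician in the same
#' connected component, by per-node BFS. Isolated nodes have eccentricity 0.
#' Larger eccentricity means more intermediaries are needed to reach the
#' farthest collaborator — the network-level reading is collaboration
#' difficulty.
#'
#' @param network a `collab_network`.
#' @return Integer hop counts named by clinician id.
#' @export
eccentricity <- function(network) {
  g <- edge_index(network)
  if (g$n == 0L) return(stats::setNames(integer(), character()))
  stats::setNames(cpp_eccentricity(g$n, g$ei - 1L, g$ej - 1L), g$ids)
}

#' Per-clinician sociometric table for one network
#'
#' @param network a `collab_network`.
#' @param weighted_eigenvector use tie weights in the eigenvector
#'   computation (default FALSE; see [eigenvector_centrality()]).
#' @return Data frame with `period`, `clinician_id`, `specialty`,
#'   `component_id`, `eigenvector`, `betweenness`, `eccentricity`.
#' @export
sociometric_table <- function(network, weighted_eigenvector = FALSE) {
  data.frame(period = network$period,
             clinician_id = network$nodes$clinician_id,
             specialty = network$nodes$specialty,
             component_id = unname(component_ids(network)),
             eigenvector = unname(eigenvector_centrality(
               network, weighted = weighted_eigenvector)),
             betweenness = unname(betweenness_centrality(network)),
             eccentricity = unname(eccentricity(network)),
             stringsAsFactors = FALSE)
}

#' Write a sociometric table to CSV
#'
#' @param table data frame from [sociometric_table()].
#' @param path output path.
#' @export
write_sociometrics <- function(table, path) {
  utils::write.csv(
    table[c("clinician_id", "specialty", "component_id",
            "eigenvector", "betweenness", "eccentricity")],
    path, row.names = FALSE)
  invisible(path)
}

#' Specialty-level summaries of a sociometric table
#'
#' For each specialty: n, median, mean and quartiles of each of the three
#' sociometrics, plus a whole-network row (specialty `"<all>"`).
#' Specialties listed in `roster` but absent from the table are emitted
#' with n = 0 and NA statistics.
#'
#' @param table data frame from [sociometric_table()].
#' @param roster optional roster whose specialty levels define the rows.
#' @return Data frame, one row per (specialty, metric).
#' @export
summarize_by_specialty <- function(table, roster = NULL) {
  specs <- sort(unique(c(table$specialty, roster$specialty)))
  metrics <- c("eigenvector", "betweenness", "eccentricity")
  rows <- list()
  for (sp in c(specs, "<all>")) {
    vals_tab <- if (sp == "<all>") table else table[table$specialty == sp, ]
    for (m in metrics) {
      v <- vals_tab[[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        specialty = sp, metric = m, n = length(v),
        median = if (length(v)) stats::median(v) else NA_real_,
        mean = if (length(v)) mean(v) else NA_real_,
        q25 = if (length(v)) unname(stats::quantile(v, 0.25)) else NA_real_,
        q75 = if (length(v)) unname(stats::quantile(v, 0.75)) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
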