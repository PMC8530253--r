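# Independent oracles and small fixture builders used across the suite.
# The oracles deliberately use different algorithms from the package:
# Floyd-Warshall for distances, recursive path enumeration for
# betweenness, a dense eigendecomposition for eigenvector centrality.

# Build a collab_network from an edge string like "a-b,b-c" (optionally
# "a-b:3" for weights) plus optional isolated nodes.
net_from_edges <- function(spec, isolated = character(), specialty = "x",
                           period = "t") {
  if (nzchar(spec)) {
    parts <- strsplit(strsplit(spec, ",", fixed = TRUE)[[1]], "[-:]")
    edges <- data.frame(
      from = vapply(parts, `[`, character(1), 1L),
      to = vapply(parts, `[`, character(1), 2L),
      weight = vapply(parts, function(p)
        if (length(p) > 2L) as.numeric(p[3L]) else 1, numeric(1)),
      stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric())
  }
  ids <- sort(unique(c(edges$from, edges$to, isolated)))
  nodes <- data.frame(clinician_id = ids,
                      specialty = rep_len(specialty, length(ids)),
                      stringsAsFactors = FALSE)
  collab_network(nodes, edges, period_label = period)
}

# Random connected graph on n nodes: random spanning tree + extra edges.
random_connected_net <- function(n, extra = 2L, weights = FALSE) {
  stopifnot(n >= 2L)
  ids <- sprintf("v%02d", seq_len(n))
  from <- integer(0); to <- integer(0)
  for (k in 2:n) {          # random spanning tree
    from <- c(from, sample.int(k - 1L, 1L)); to <- c(to, k)
  }
  for (k in seq_len(extra)) {
    pair <- sample.int(n, 2L)
    from <- c(from, pair[1L]); to <- c(to, pair[2L])
  }
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- !duplicated(paste(a, b)) & a != b
  edges <- data.frame(from = ids[a[keep]], to = ids[b[keep]],
                      weight = if (weights)
                        sample.int(5L, sum(keep), replace = TRUE)
                      else rep(1, sum(keep)),
                      stringsAsFactors = FALSE)
  collab_network(data.frame(clinician_id = ids, specialty = "x",
                            stringsAsFactors = FALSE), edges)
}

net_dense_adjacency <- function(net, weighted = FALSE) {
  ids <- net$nodes$clinician_id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  i <- match(net$edges$from, ids); j <- match(net$edges$to, ids)
  w <- if (weighted) net$edges$weight else rep(1, length(i))
  A[cbind(i, j)] <- w; A[cbind(j, i)] <- w
  A
}

# All-pairs hop distances by Floyd-Warshall.
oracle_distances <- function(net) {
  A <- net_dense_adjacency(net)
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf); diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

oracle_eccentricity <- function(net) {
  D <- oracle_distances(net)
  apply(D, 1L, function(r) max(r[is.finite(r)]))
}

# Betweenness by explicit enumeration of all shortest paths (distance-
# decreasing recursive descent), normalised per component.
oracle_betweenness <- function(net) {
  D <- oracle_distances(net)
  ids <- net$nodes$clinician_id
  n <- length(ids)
  A <- net_dense_adjacency(net) > 0
  count_through <- function(s, t) {
    # returns c(n_paths, through counts per node)
    through <- numeric(n)
    recurse <- function(v, visited) {
      if (v == t) {
        through[visited] <<- through[visited] + 1
        return(1)
      }
      total <- 0
      for (u in which(A[v, ])) {
        if (D[u, t] == D[v, t] - 1) total <- total + recurse(u, c(visited, u))
      }
      total
    }
    npaths <- recurse(s, integer(0))
    through[c(s, t)] <- 0
    list(npaths = npaths, through = through)
  }
  raw <- numeric(n)
  for (s in seq_len(n - 1L)) for (t in seq(s + 1L, n)) {
    if (!is.finite(D[s, t]) || D[s, t] == 0) next
    r <- count_through(s, t)
    raw <- raw + r$through / r$npaths
  }
  comp <- component_ids(net)
  for (cc in unique(comp)) {
    m <- which(comp == cc); nc <- length(m)
    raw[m] <- if (nc > 2L) raw[m] / ((nc - 1) * (nc - 2) / 2) else 0
  }
  stats::setNames(raw, ids)
}

# Leading eigenvector per component from a dense eigendecomposition,
# max-normalised within components.
oracle_eigenvector <- function(net, weighted = FALSE) {
  A <- net_dense_adjacency(net, weighted = weighted)
  comp <- component_ids(net)
  out <- numeric(nrow(A))
  for (cc in unique(comp)) {
    m <- which(comp == cc)
    if (length(m) == 1L) next
    e <- eigen(A[m, m, drop = FALSE], symmetric = TRUE)
    v <- abs(e$vectors[, 1L])
    out[m] <- v / max(v)
  }
  stats::setNames(out, net$nodes$clinician_id)
}

# Tiny event-table builder: rows of "clinician specialty patient day".
events_from_rows <- function(...) {
  rows <- strsplit(c(...), "\\s+")
  df <- data.frame(
    clinician_id = vapply(rows, `[`, character(1), 1L),
    specialty = vapply(rows, `[`, character(1), 2L),
    patient_id = vapply(rows, `[`, character(1), 3L),
    timestamp = vapply(rows, `[`, character(1), 4L),
    action_category = "note",
    stringsAsFactors = FALSE)
  collabnet:::validate_events(df)
}
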