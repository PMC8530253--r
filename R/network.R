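# Projection of patient-day units into the weighted undirected clinician
# collaboration network, plus summary statistics and graph-file IO.

#' Build a clinician collaboration network
#'
#' Two clinicians are tied iff they both hold a patient-day unit for the
#' same patient on the same calendar day; the tie weight is the number of
#' distinct (patient, day) pairs they share — the cumulative number of
#' patient days on which they interacted. Clinicians appearing in
#' `patient_days` but sharing no patient day remain as isolated nodes:
#' network membership is defined by activity, not connectivity.
#'
#' @param patient_days data frame from [to_patient_days()] (one period).
#' @param roster data frame with `clinician_id` and `specialty`; must cover
#'   every clinician in `patient_days` (missing ids are a hard error).
#' @param period_label label stored on the network (e.g. `"pre"`).
#' @param min_weight drop edges with weight below this (default 1 = keep all).
#' @return A `collab_network`: list with `period`, `nodes` (data frame
#'   `clinician_id`, `specialty`) and `edges` (data frame `from`, `to`,
#'   `weight`, with `from < to` lexicographically).
#' @export
build_network <- function(patient_days, roster, period_label = "", min_weight = 1L) {
  pd <- unique(patient_days[c("clinician_id", "patient_id", "day")])
  ids <- sort(unique(pd$clinician_id))
  missing <- setdiff(ids, roster$clinician_id)
  if (length(missing) > 0L) {
    stop("clinician id(s) missing from roster: ", paste(missing, collapse = ", "))
  }
  nodes <- data.frame(clinician_id = ids,
                      specialty = roster$specialty[match(ids, roster$clinician_id)],
                      stringsAsFactors = FALSE)

  if (nrow(pd) > 0L) {
    pd$.pday <- paste(pd$patient_id, pd$day, sep = "\r")
    m <- merge(pd[c("clinician_id", ".pday")], pd[c("clinician_id", ".pday")],
               by = ".pday", suffixes = c(".a", ".b"))
    m <- m[m$clinician_id.a < m$clinician_id.b, , drop = FALSE]
  } else {
    m <- data.frame(clinician_id.a = character(), clinician_id.b = character())
  }
  if (nrow(m) > 0L) {
    key <- paste(m$clinician_id.a, m$clinician_id.b, sep = "\r")
    w <- table(key)  # each row is one distinct shared (patient, day)
    parts <- strsplit(names(w), "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(parts, `[`, character(1), 1L),
                        to = vapply(parts, `[`, character(1), 2L),
                        weight = as.integer(w), stringsAsFactors = FALSE)
    edges <- edges[edges$weight >= min_weight, , drop = FALSE]
    edges <- edges[order(edges$from, edges$to, method = "radix"), , drop = FALSE]
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = integer(), stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  structure(list(period = period_label, nodes = nodes, edges = edges),
            class = "collab_network")
}

#' Construct a collaboration network from explicit node and edge tables
#'
#' Low-level constructor used by readers and tests; [build_network()] is the
#' normal entry point.
#'
#' @param nodes data frame `clinician_id`, `specialty`.
#' @param edges data frame `from`, `to`, `weight`.
#' @param period_label network label.
#' @export
collab_network <- function(nodes, edges, period_label = "") {
  stopifnot(all(c("clinician_id", "specialty") %in% names(nodes)),
            all(c("from", "to", "weight") %in% names(edges)))
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
  bad <- setdiff(c(edges$from, edges$to), nodes$clinician_id)
  if (length(bad) > 0L) stop("edge endpoint(s) not in node set: ",
                             paste(bad, collapse = ", "))
  if (any(edges$weight <= 0)) stop("edge weights must be positive")
  edges <- edges[order(edges$from, edges$to, method = "radix"), , drop = FALSE]
  nodes <- nodes[order(nodes$clinician_id, method = "radix"), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(period = period_label, nodes = nodes, edges = edges),
            class = "collab_network")
}

#' @export
print.collab_network <- function(x, ...) {
  cat("collab_network", if (nzchar(x$period)) paste0("[", x$period, "]"), "-",
      nrow(x$nodes), "clinicians,", nrow(x$edges), "ties, total weight",
      sum(x$edges$weight), "\n")
  invisible(x)
}

#' Summary statistics of a collaboration network
#'
#' @param network a `collab_network`.
#' @return List with node/edge counts, total edge weight, per-specialty node
#'   counts, and connected-component count and sizes.
#' @export
network_stats <- function(network) {
  comp <- component_ids(network)
  sizes <- if (length(comp) > 0L) as.integer(table(comp)) else integer()
  list(period = network$period,
       n_nodes = nrow(network$nodes),
       n_edges = nrow(network$edges),
       total_weight = sum(network$edges$weight),
       specialty_counts = if (nrow(network$nodes) > 0L)
         table(network$nodes$specialty) else table(character()),
       n_components = length(sizes),
       component_sizes = sort(sizes, decreasing = TRUE))
}

#' Convert a collaboration network to an igraph object
#'
#' Used for graph-file interop; all sociometrics in this package are computed
#' by its own routines, not igraph's.
#'
#' @param network a `collab_network`.
#' @return An undirected weighted `igraph` graph with vertex attribute
#'   `specialty` and edge attribute `weight`.
#' @export
as_igraph <- function(network) {
  vert <- data.frame(name = network$nodes$clinician_id,
                     specialty = network$nodes$specialty,
                     stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(network$edges, directed = FALSE, vertices = vert)
}

#' Export a collaboration network to a graph file
#'
#' GraphML and GEXF carry the `specialty` node attribute and `weight` edge
#' attribute and load in standard graph tools (e.g. Gephi); the edge-list
#' CSV (`source,target,weight`) round-trips through
#' [read_network_edgelist()].
#'
#' @param network a `collab_network`.
#' @param path output file.
#' @param format one of `"graphml"`, `"gexf"`, `"edgelist"`.
#' @export
write_network <- function(network, path, format = c("graphml", "gexf", "edgelist")) {
  format <- match.arg(format)
  switch(format,
    graphml = igraph::write_graph(as_igraph(network), path, format = "graphml"),
    gexf = write_gexf(network, path),
    edgelist = utils::write.csv(
      data.frame(source = network$edges$from, target = network$edges$to,
                 weight = network$edges$weight),
      path, row.names = FALSE, quote = FALSE))
  invisible(path)
}

write_gexf <- function(network, path) {
  doc <- xml2::xml_new_root("gexf",
    xmlns = "http://www.gexf.net/1.2draft", version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(attrs, "attribute", id = "0", title = "specialty",
                      type = "string")
  nodes <- xml2::xml_add_child(graph, "nodes")
  for (i in seq_len(nrow(network$nodes))) {
    nd <- xml2::xml_add_child(nodes, "node",
                              id = network$nodes$clinician_id[i],
                              label = network$nodes$clinician_id[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0",
                        value = network$nodes$specialty[i])
  }
  edges <- xml2::xml_add_child(graph, "edges")
  for (i in seq_len(nrow(network$edges))) {
    xml2::xml_add_child(edges, "edge", id = as.character(i - 1L),
                        source = network$edges$from[i],
                        target = network$edges$to[i],
                        weight = as.character(network$edges$weight[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a collaboration network from an edge-list CSV
#'
#' @param path CSV with columns `source,target,weight`.
#' @param roster optional data frame `clinician_id`, `specialty` supplying
#'   node labels (and any isolated nodes); without it, specialties are
#'   `"unknown"` and only clinicians on an edge appear.
#' @param period_label label stored on the network.
#' @export
read_network_edgelist <- function(path, roster = NULL, period_label = "") {
  el <- utils::read.csv(path, colClasses = c("character", "character", "numeric"))
  names(el) <- c("from", "to", "weight")
  ids <- sort(unique(c(el$from, el$to, roster$clinician_id)))
  specialty <- if (is.null(roster)) rep("unknown", length(ids)) else {
    sp <- roster$specialty[match(ids, roster$clinician_id)]
    ifelse(is.na(sp), "unknown", sp)
  }
  collab_network(data.frame(clinician_id = ids, specialty = specialty,
                            stringsAsFactors = FALSE),
                 el, period_label = period_label)
}

#' Read a collaboration network from a GraphML file
#'
#' @param path GraphML file with a `specialty` vertex attribute and `weight`
#'   edge attribute, e.g. written by [write_network()].
#' @param period_label label stored on the network.
#' @export
read_network_graphml <- function(path, period_label = "") {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(clinician_id = igraph::V(g)$name,
                      specialty = if ("specialty" %in%
                                      igraph::vertex_attr_names(g))
                        igraph::V(g)$specialty else "unknown",
                      stringsAsFactors = FALSE)
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- data.frame(from = el$from, to = el$to,
                      weight = if ("weight" %in% names(el)) el$weight else 1,
                      stringsAsFactors = FALSE)
  collab_network(nodes, edges, period_label = period_label)
}
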