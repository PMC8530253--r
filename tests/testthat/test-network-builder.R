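# Patient-day projection into the weighted collaboration network.

pd_from_rows <- function(...) {
  rows <- strsplit(c(...), "\\s+")
  data.frame(clinician_id = vapply(rows, `[`, character(1), 1L),
             patient_id = vapply(rows, `[`, character(1), 2L),
             day = as.Date(vapply(rows, `[`, character(1), 3L)),
             stringsAsFactors = FALSE)
}

roster_for <- function(pd) {
  data.frame(clinician_id = unique(pd$clinician_id), specialty = "x",
             stringsAsFactors = FALSE)
}

test_that("ties require a shared (patient, day); same patient different day is no tie", {
  pd <- pd_from_rows("c1 p1 2019-09-01", "c2 p1 2019-09-01",
                     "c2 p2 2019-09-01", "c3 p2 2019-09-02")
  net <- build_network(pd, roster_for(pd))
  expect_equal(net$edges$from, "c1")
  expect_equal(net$edges$to, "c2")
  expect_equal(net$edges$weight, 1L)
  expect_setequal(net$nodes$clinician_id, c("c1", "c2", "c3"))  # c3 isolated
  expect_equal(unname(component_ids(net)[["c3"]]), 2L)
})

test_that("weight accumulates one unit per distinct shared patient day", {
  pd <- pd_from_rows("c1 p1 2019-09-01", "c2 p1 2019-09-01",
                     "c1 p1 2019-09-02", "c2 p1 2019-09-02",
                     "c1 p2 2019-09-01", "c2 p2 2019-09-01")
  net <- build_network(pd, roster_for(pd))
  expect_equal(net$edges$weight, 3L)
  # duplicated units do not inflate weights
  net2 <- build_network(rbind(pd, pd), roster_for(pd))
  expect_equal(net2$edges$weight, 3L)
})

test_that("a single clinician yields one node and no edges", {
  pd <- pd_from_rows("c1 p1 2019-09-01", "c1 p2 2019-09-03")
  net <- build_network(pd, roster_for(pd))
  expect_equal(nrow(net$nodes), 1L)
  expect_equal(nrow(net$edges), 0L)
})

test_that("a clinician missing from the roster is a hard error listing ids", {
  pd <- pd_from_rows("c1 p1 2019-09-01", "c9 p1 2019-09-01")
  expect_error(build_network(pd, data.frame(clinician_id = "c1",
                                            specialty = "x")), "c9")
})

test_that("total weight equals the brute-force co-occurrence triple count", {
  # property over random patient-day sets
  for (s in 1:20) {
    set.seed(1000 + s)
    pd <- unique(data.frame(
      clinician_id = sprintf("c%d", sample.int(8, 60, replace = TRUE)),
      patient_id = sprintf("p%d", sample.int(5, 60, replace = TRUE)),
      day = as.Date("2019-09-01") + sample.int(6, 60, replace = TRUE),
      stringsAsFactors = FALSE))
    net <- build_network(pd, roster_for(pd))
    # oracle: sum over (patient, day) groups of choose(k, 2)
    k <- table(paste(pd$patient_id, pd$day))
    expect_equal(sum(net$edges$weight), sum(choose(k, 2)))
  }
})

test_that("relabeling clinicians yields an isomorphic network", {
  set.seed(7)
  pd <- unique(data.frame(
    clinician_id = sprintf("c%d", sample.int(6, 40, replace = TRUE)),
    patient_id = sprintf("p%d", sample.int(4, 40, replace = TRUE)),
    day = as.Date("2019-09-01") + sample.int(5, 40, replace = TRUE),
    stringsAsFactors = FALSE))
  net <- build_network(pd, roster_for(pd))
  relabel <- stats::setNames(sprintf("z%02d", sample.int(6)),
                             sprintf("c%d", 1:6))
  pd2 <- transform(pd, clinician_id = unname(relabel[clinician_id]))
  net2 <- build_network(pd2, roster_for(pd2))
  expect_equal(nrow(net2$edges), nrow(net$edges))
  key1 <- sort(paste(relabel[net$edges$from], relabel[net$edges$to],
                     net$edges$weight))
  key1 <- sort(vapply(strsplit(key1, " "), function(p)
    paste(sort(p[1:2])[1], sort(p[1:2])[2], p[3]), character(1)))
  key2 <- sort(paste(net2$edges$from, net2$edges$to, net2$edges$weight))
  expect_identical(key1, key2)
})

test_that("adding a patient-day unit never decreases weights or drops edges", {
  set.seed(11)
  pd <- unique(data.frame(
    clinician_id = sprintf("c%d", sample.int(5, 25, replace = TRUE)),
    patient_id = sprintf("p%d", sample.int(3, 25, replace = TRUE)),
    day = as.Date("2019-09-01") + sample.int(4, 25, replace = TRUE),
    stringsAsFactors = FALSE))
  roster <- data.frame(clinician_id = sprintf("c%d", 1:5), specialty = "x")
  net1 <- build_network(pd, roster)
  extra <- data.frame(clinician_id = "c1", patient_id = "p1",
                      day = as.Date("2019-09-02"))
  net2 <- build_network(rbind(pd, extra), roster)
  key1 <- paste(net1$edges$from, net1$edges$to)
  key2 <- paste(net2$edges$from, net2$edges$to)
  expect_true(all(key1 %in% key2))
  expect_true(all(net2$edges$weight[match(key1, key2)] >= net1$edges$weight))
})

test_that("network_stats summarises counts, weights and components", {
  empty <- build_network(pd_from_rows(character(0))[0, ],
                         data.frame(clinician_id = character(),
                                    specialty = character()))
  st <- network_stats(empty)
  expect_equal(st$n_nodes, 0L); expect_equal(st$n_edges, 0L)
  expect_equal(st$total_weight, 0L); expect_equal(st$n_components, 0L)

  tri <- net_from_edges("a-b,b-c,a-c")
  st <- network_stats(tri)
  expect_equal(st$n_nodes, 3L); expect_equal(st$n_edges, 3L)
  expect_equal(st$total_weight, 3); expect_equal(st$n_components, 1L)

  dyads <- net_from_edges("a-b,c-d")
  st <- network_stats(dyads)
  expect_equal(st$n_components, 2L)
  expect_equal(unname(st$component_sizes), c(2L, 2L))
})

test_that("graph exports round-trip and carry specialties and weights", {
  net <- net_from_edges("a-b:3,b-c:1")
  net$nodes$specialty <- c("nurse", "doc", "rt")

  f_el <- tempfile(fileext = ".csv")
  write_network(net, f_el, format = "edgelist")
  rt <- read_network_edgelist(f_el, roster = data.frame(
    clinician_id = net$nodes$clinician_id,
    specialty = net$nodes$specialty))
  expect_equal(rt$edges, net$edges)
  expect_equal(rt$nodes, net$nodes)

  f_gml <- tempfile(fileext = ".graphml")
  write_network(net, f_gml, format = "graphml")
  rt2 <- read_network_graphml(f_gml)
  expect_equal(rt2$edges[c("from", "to")], net$edges[c("from", "to")])
  expect_equal(as.numeric(rt2$edges$weight), as.numeric(net$edges$weight))
  expect_equal(rt2$nodes, net$nodes)

  f_gexf <- tempfile(fileext = ".gexf")
  write_network(net, f_gexf, format = "gexf")
  doc <- xml2::read_xml(f_gexf)
  ns <- xml2::xml_ns(doc)
  expect_equal(length(xml2::xml_find_all(doc, "//d1:node", ns)), 3L)
  expect_equal(length(xml2::xml_find_all(doc, "//d1:edge", ns)), 2L)
  expect_setequal(
    xml2::xml_attr(xml2::xml_find_all(doc, "//d1:attvalue", ns), "value"),
    c("nurse", "doc", "rt"))
})
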