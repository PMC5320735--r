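# OBO parsing, DAG closure, propagation and counting semantics

test_that("parse_obo reads stanzas, relations and degenerate inputs", {
  g <- chain_graph()
  expect_s3_class(g, "ontology_graph")
  expect_equal(nrow(g$terms), 3)
  expect_equal(nrow(g$relations), 2)

  empty <- parse_obo(c("format-version: 1.2", "ontology: none"))
  expect_equal(nrow(empty$terms), 0)
  expect_equal(nrow(empty$relations), 0)

  obsolete <- parse_obo(c("[Term]", "id: O:1", "name: live", "",
                          "[Term]", "id: O:2", "name: dead",
                          "is_obsolete: true"))
  expect_true(obsolete$terms$is_obsolete[obsolete$terms$term_id == "O:2"])

  # unknown relationship labels are preserved as their own predicate
  other <- parse_obo(c("[Term]", "id: X:1", "name: a", "",
                       "[Term]", "id: X:2", "name: b",
                       "relationship: regulates X:1"))
  expect_equal(other$relations$predicate, "regulates")
  # and do not propagate
  expect_equal(ancestors(other, "X:2"), character())
})

test_that("parse_obo rejects cycles, dangling relations and duplicate ids", {
  expect_error(parse_obo(c("[Term]", "id: C:A", "name: a", "is_a: C:B", "",
                           "[Term]", "id: C:B", "name: b", "is_a: C:A")),
               "cycle.*C:A.*C:B")
  expect_error(parse_obo(c("[Term]", "id: C:A", "name: a", "is_a: C:Z")),
               "C:Z")
  expect_error(parse_obo(c("[Term]", "id: C:A", "name: a", "",
                           "[Term]", "id: C:A", "name: a2")),
               "duplicate")
})

test_that("ancestors walks chains, roots and diamonds", {
  g <- chain_graph()
  expect_equal(ancestors(g, "T:2"), c("T:0", "T:1"))
  expect_equal(ancestors(g, "T:0"), character())
  expect_error(ancestors(g, "T:9"), "not found")

  d <- diamond_graph()
  expect_setequal(ancestors(d, "D:D"), c("D:B", "D:C", "D:A"))
  expect_equal(sum(ancestors(d, "D:D") == "D:A"), 1)  # A listed once
})

test_that("ancestors equals the boolean-matrix closure on random DAGs", {
  for (seed in 1:30) {
    n <- 5 + (seed %% 46)
    dag <- rand_dag(n, seed)
    for (i in seq_len(n)) {
      expect_equal(ancestors(dag$graph, dag$id(i)),
                   sort(dag$id(which(dag$reach[i, ]))),
                   info = paste("seed", seed, "node", i))
    }
  }
})

test_that("propagation separates direct from inherited and handles obsoletes", {
  g <- chain_graph()
  out <- propagate_annotations(g, list(F1 = "T:2"))
  expect_setequal(out$term_id[out$status == "direct"], "T:2")
  expect_setequal(out$term_id[out$status == "inherited"], c("T:1", "T:0"))

  d <- diamond_graph()
  out <- propagate_annotations(d, list(F = c("D:B", "D:C")))
  inh <- out$term_id[out$status == "inherited"]
  expect_equal(inh, "D:A")  # once, despite two paths

  expect_equal(nrow(propagate_annotations(g, list())), 0)

  # direct/inherited disjoint on random annotation maps
  for (seed in 31:36) {
    dag <- rand_dag(20, seed)
    ann <- withr::with_seed(seed, {
      stats::setNames(lapply(1:6, function(i) dag$id(sample.int(20, 3))),
                      paste0("f", 1:6))
    })
    out <- propagate_annotations(dag$graph, ann)
    per <- split(out, out$feature)
    for (x in per) {
      expect_length(intersect(x$term_id[x$status == "direct"],
                              x$term_id[x$status == "inherited"]), 0)
    }
  }

  og <- parse_obo(c("[Term]", "id: O:1", "name: root", "",
                    "[Term]", "id: O:2", "name: dead", "is_obsolete: true"))
  expect_warning(out <- propagate_annotations(og, list(F = c("O:2"))),
                 "obsolete")
  expect_equal(out$status, "direct")  # kept, not inherited from
  expect_error(propagate_annotations(og, list(F = "O:99")), "unknown term")
})

test_that("term counts use distinct-feature membership with multi-annotation overlap", {
  g <- chain_graph()
  prop <- propagate_annotations(g, list(F1 = "T:2", F2 = "T:1"))
  s <- term_count_summary(g, prop, "T:0")
  expect_equal(s$term_id, "T:1")
  expect_equal(s$n_features, 2L)
  expect_equal(attr(s, "total"), 2L)

  d <- diamond_graph()
  prop <- propagate_annotations(d, list(F = c("D:B", "D:C")))
  s <- term_count_summary(d, prop, "D:A")
  expect_equal(sort(s$term_id), c("D:B", "D:C"))
  expect_equal(s$n_features, c(1L, 1L))
  expect_equal(attr(s, "total"), 1L)       # slice sum 2 > total 1
  expect_gt(sum(s$n_features), attr(s, "total"))

  s0 <- term_count_summary(d, propagate_annotations(d, list()), "D:A")
  expect_true(all(s0$n_features == 0))
  expect_error(term_count_summary(d, prop, "D:Z"), "not found")
})

test_that("counts are monotone up the DAG and complete at the root", {
  for (seed in 41:45) {
    n <- 25
    dag <- rand_dag(n, seed)
    ann <- withr::with_seed(seed + 100, {
      stats::setNames(lapply(1:8, function(i) dag$id(sample(2:n, 2))),
                      paste0("f", 1:8))
    })
    prop <- propagate_annotations(dag$graph, ann)
    sets <- split(prop$term_id, prop$feature)
    n_at <- function(t) sum(vapply(sets, function(s) t %in% s, logical(1)))
    rel <- dag$graph$relations
    for (r in seq_len(nrow(rel))) {
      expect_gte(n_at(rel$object_id[r]), n_at(rel$subject_id[r]))
    }
    # root completeness: everything reaches node 1
    expect_equal(n_at(dag$id(1)), length(ann))
  }
})

test_that("dbxref mapping is set-valued and reports the unmapped", {
  path <- withr::local_tempfile(lines = c(
    "! interpro2go style comments are ignored",
    "# and hash comments too",
    "IPR000001\tGO:0008150",
    "IPR000002\tGO:0003674"))
  map <- read_dbxref_map(path)
  expect_equal(nrow(map), 2)
  expect_equal(map_dbxref(map, "IPR000001")$term_ids, "GO:0008150")
  miss <- map_dbxref(map, "IPR999999")
  expect_equal(miss$term_ids, character())
  expect_equal(miss$unmapped, "IPR999999")
  # idempotent set semantics
  expect_equal(map_dbxref(map, c("IPR000001", "IPR000001"))$term_ids,
               "GO:0008150")

  bad <- withr::local_tempfile(lines = c("IPR000001\tGO:1", "only-one-column"))
  expect_warning(m2 <- read_dbxref_map(bad), "line 2")
  expect_equal(nrow(m2), 1)
})

test_that("annotation subgraph induces ancestors with status flags, idempotently", {
  g <- chain_graph()
  sub <- annotation_subgraph(g, "T:2")
  expect_setequal(sub$terms$term_id, c("T:2", "T:1", "T:0"))
  expect_equal(nrow(sub$relations), 2)
  expect_equal(sub$terms$status[sub$terms$term_id == "T:2"], "direct")
  expect_equal(sub$terms$status[sub$terms$term_id == "T:0"], "inherited")

  empty <- annotation_subgraph(g, character())
  expect_equal(nrow(empty$terms), 0)

  d <- diamond_graph()
  sub <- annotation_subgraph(d, "D:B")
  expect_setequal(sub$terms$term_id, c("D:B", "D:A"))
  expect_equal(nrow(sub$relations), 1)   # C excluded

  # idempotence on its own node set
  again <- annotation_subgraph(sub, sub$terms$term_id)
  expect_setequal(again$terms$term_id, sub$terms$term_id)
  expect_equal(dplyr::arrange(again$relations, subject_id, object_id),
               dplyr::arrange(sub$relations, subject_id, object_id))
  expect_error(annotation_subgraph(g, "T:9"), "not found")
})
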