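# search surface, combined filters, reports

test_that("name search supports like/exact/regex with SQL wildcards", {
  store <- tiny_store(5)
  all <- search_by_name(store, "%", mode = "like")
  expect_equal(nrow(all), 5)
  expect_equal(all$unique_name, sort(all$unique_name))  # deterministic order
  expect_equal(nrow(search_by_name(store, "isotig001", mode = "exact")), 1)
  expect_equal(nrow(search_by_name(store, "isotig00_", mode = "like")), 5)
  expect_equal(nrow(search_by_name(store, "^isotig00[12]$", mode = "regex")), 2)
  expect_equal(nrow(search_by_name(store, "ISOTIG001", mode = "exact")), 1)
  expect_equal(nrow(search_by_name(store, "ISOTIG001", mode = "exact",
                                   ignore_case = FALSE)), 0)
  expect_error(search_by_name(store, "([", mode = "regex"), "invalid regular")
})

test_that("term search flags direct vs indirect with direct precedence", {
  store <- tiny_store(2)
  g <- chain_graph()
  load_ontology(store, g, name = "T")
  add_term_annotation(store, "isotig001", "T:2")
  q <- search_by_term(store, g, "T:1", include_inherited = TRUE)
  expect_equal(nrow(q), 1)
  expect_equal(q$flag, "indirect")
  expect_equal(nrow(search_by_term(store, g, "T:1", include_inherited = FALSE)), 0)
  q2 <- search_by_term(store, g, "T:2")
  expect_equal(q2$flag, "direct")
  # annotated both at the term and below it -> direct wins
  add_term_annotation(store, "isotig001", "T:1")
  q3 <- search_by_term(store, g, "T:1")
  expect_equal(nrow(q3), 1)
  expect_equal(q3$flag, "direct")
  expect_error(search_by_term(store, g, "T:9"), "not found")
})

test_that("term search equals a brute-force membership scan on the fixture", {
  fx <- loaded_toy_store()
  store <- fx$store
  g <- get_ontology(store, "TGO")
  ann <- fx$manifest$annotations      # feature -> direct terms (ground truth)
  reach_terms <- function(terms) {
    unique(c(terms, unlist(lapply(terms, ancestors, graph = g))))
  }
  for (term in c(fx$manifest$focus_term, "TGO:0000002", "TGO:0000004")) {
    expected <- sort(names(ann)[vapply(ann, function(ts)
      term %in% reach_terms(ts), logical(1))])
    got <- search_by_term(store, g, term)
    expect_equal(sort(got$unique_name), expected, info = term)
  }
})

test_that("blast description search deduplicates query features", {
  store <- tiny_store(2)
  a <- add_analysis(store, "blastx")
  for (i in 1:2) {
    txforge:::add_blast_hit(store, "isotig001", paste0("A", i),
                            "protein kinase domain", 1e-10, 100, 90, 0, 50,
                            analysis_id = a)
  }
  txforge:::add_blast_hit(store, "isotig002", "B1", "hypothetical protein",
                          1e-5, 50, 80, 0, 50, analysis_id = a)
  q <- search_by_blast_description(store, "%kinase%")
  expect_equal(nrow(q), 1)   # two matching hits, one feature
  expect_equal(q$unique_name, "isotig001")
  expect_equal(nrow(search_by_blast_description(store, "%zinc finger%")), 0)

  fx <- loaded_toy_store()
  qk <- search_by_blast_description(fx$store, "%kinase%")
  expect_setequal(qk$unique_name, fx$manifest$kinase_features)
})

test_that("marker filter keeps features with enough markers and is idempotent", {
  fx <- loaded_toy_store()
  store <- fx$store
  all_tx <- search_by_name(store, "%", so_type = "SO:0000149")
  f1 <- filter_by_marker(all_tx, store, "SSR", min_count = 1)
  expect_setequal(f1$unique_name, fx$manifest$ssr_transcripts)
  expect_true(all(f1$n_markers >= 1))
  f2 <- filter_by_marker(f1, store, "SSR", min_count = 1)
  expect_equal(as.data.frame(f2)[names(f1)], as.data.frame(f1)[names(f1)])
  # min_count above the fixture's one-SSR-per-transcript design excludes all
  expect_equal(nrow(filter_by_marker(all_tx, store, "SSR", min_count = 2)), 0)
  empty <- search_by_name(store, "zzz-none", mode = "exact")
  expect_equal(nrow(filter_by_marker(empty, store, "SSR")), 0)
})

test_that("result-restricted term summaries match the unrestricted on full sets", {
  fx <- loaded_toy_store()
  store <- fx$store
  g <- get_ontology(store, "TGO")
  all_tx <- search_by_name(store, "%", so_type = "SO:0000149")
  restricted <- term_summary_for_result(all_tx, store, g, "TGO:0000001")
  full <- term_count_summary(
    g, txforge:::store_propagated(store, g), "TGO:0000001")
  expect_equal(tibble::as_tibble(restricted), tibble::as_tibble(full))
  expect_equal(attr(restricted, "total"), attr(full, "total"))
  # counts against the generator's brute-force ground truth
  truth <- fx$manifest$root_child_counts
  for (ch in restricted$term_id) {
    expect_equal(restricted$n_features[restricted$term_id == ch],
                 truth[[ch]], info = ch)
  }
  # disjoint result -> all zero
  none <- search_by_name(store, "isogroup01", mode = "exact")
  z <- term_summary_for_result(none, store, g, "TGO:0000001")
  expect_true(all(z$n_features == 0))
})

test_that("case-study replay equals the brute-force intersection", {
  fx <- loaded_toy_store()
  q <- case_study_query(fx$store, fx$manifest$focus_term)
  expect_equal(sort(q$unique_name), sort(fx$manifest$ssr_under_focus))
  # and equals recomputing the two sides independently
  by_hand <- intersect(fx$manifest$ssr_transcripts, fx$manifest$under_focus)
  expect_setequal(q$unique_name, by_hand)
})

test_that("sequence reports have six sections, or relationships-only without residues", {
  fx <- loaded_toy_store()
  store <- fx$store
  tig <- fx$manifest$kinase_features[1]   # has blast + annot + expression
  rep <- sequence_report(store, tig)
  expect_named(rep$sections,
               c("residues", "relationships", "structural_annotation",
                 "functional_annotation", "blast_results", "expression_results"))
  expect_gt(nrow(rep$sections$relationships), 0)
  expect_gt(nrow(rep$sections$structural_annotation), 0)
  expect_gt(nrow(rep$sections$blast_results), 0)
  expect_gt(nrow(rep$sections$expression_results), 0)
  expect_gt(nrow(rep$sections$functional_annotation$direct), 0)
  sub <- rep$sections$functional_annotation$subgraph
  expect_s3_class(sub, "ontology_graph")
  expect_true(all(c("direct", "inherited") %in% sub$terms$status) ||
                all(sub$terms$status == "direct"))

  # residue-less isogroup: general report, relationships only
  grep_ <- sequence_report(store, "isogroup01")
  expect_named(grep_$sections, "relationships")
  expect_gt(nrow(grep_$sections$relationships), 0)

  # empty sections are present but empty on a bare transcript
  bare <- tiny_store(1)
  brep <- sequence_report(bare, "isotig001")
  expect_length(brep$sections, 6)
  expect_equal(nrow(brep$sections$blast_results), 0)
  expect_error(sequence_report(store, "nosuch"), "unknown feature")
})

test_that("marker, experiment and genotype reports expose design and alleles", {
  fx <- loaded_toy_store()
  store <- fx$store
  # marker report: location + per-genotype alleles
  mk <- store$tables$marker
  snp <- mk$marker_id[mk$marker_type == "SNP"][1]
  mrep <- marker_report(store, snp)
  expect_equal(nrow(mrep$location), 1)
  al <- store$tables$allele
  expect_equal(nrow(mrep$alleles), sum(al$marker_id == snp))

  erep <- experiment_report(store, "male_larvae")
  expect_equal(nrow(erep$libraries), 1)     # one library per condition
  expect_equal(nrow(erep$condition_terms), 2)

  grep_ <- genotype_report(store, "lineA")
  expect_equal(nrow(grep_$attributes), 1)
  expect_true(all(grep_$alleles$marker %in%
                    store$tables$feature$unique_name))
  # genotype with no alleles still reports attributes
  add_genotype(store, "lineC",
               tibble::tibble(term_id = "THAO:0000004", value = NA))
  g0 <- genotype_report(store, "lineC")
  expect_equal(nrow(g0$alleles), 0)
  expect_equal(nrow(g0$attributes), 1)

  js <- report_json(erep)
  expect_true(jsonlite::validate(js))
})

test_that("query results serialize and autoplots build", {
  fx <- loaded_toy_store()
  q <- search_by_name(fx$store, "%", so_type = "SO:0000149")
  csv <- export_table(q)
  expect_equal(length(strsplit(csv, "\n")[[1]]) - 1L, nrow(q))
  g <- glance(q)
  expect_equal(g$n_features, nrow(q))

  prof <- expression_profile(fx$store, fx$manifest$planted_isotigs[1],
                             measure = "RPKM")
  p <- autoplot(prof)
  expect_s3_class(p, "ggplot")
  ts <- term_summary_for_result(q, fx$store, get_ontology(fx$store, "TGO"),
                                "TGO:0000001")
  expect_s3_class(autoplot(ts), "ggplot")
})
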