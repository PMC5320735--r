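# store administration: schema metadata, typed writes, cascade delete,
# backup/restore

test_that("a fresh store exposes the five core and seven additional module groups", {
  store <- init_store(tempfile(fileext = ".txdb"))
  mods <- tx_modules(store)
  expect_equal(dplyr::n_distinct(mods$module), 12)
  expect_equal(dplyr::n_distinct(mods$module[mods$core]), 5)
  expect_setequal(unique(mods$module[mods$core]),
                  c("Sequence", "General", "Publication", "Audit",
                    "Controlled vocabularies"))
  expect_setequal(unique(mods$module[!mods$core]),
                  c("Organism", "Companalysis", "Phenotype", "Strain",
                    "Genetics", "Stock", "Expression"))
  expect_equal(nrow(store$tables$feature), 0)
  # every table is reachable through the metadata
  for (tb in mods$table) expect_s3_class(tx_table(store, tb), "tbl_df")
})

test_that("init refuses to clobber and overwrites only on request", {
  path <- tempfile(fileext = ".txdb")
  store <- init_store(path)
  add_organism(store, "Toyia", "exempli")
  upsert_feature(store, "t1", "SO:0000149", "Toyia exempli", residues = "ACGT")
  tx_save(store)
  expect_error(init_store(path), "already exists")
  fresh <- init_store(path, overwrite = TRUE)
  expect_equal(nrow(fresh$tables$feature), 0)
})

test_that("upsert is idempotent, derives seqlen, and updates in place", {
  store <- tiny_store(0)
  res <- strrep("ACGTACGTAC", 100)
  id1 <- upsert_feature(store, "tx1", "SO:0000149", "Toyia exempli",
                        residues = res)
  expect_equal(store$tables$feature$seqlen, 1000L)
  id2 <- upsert_feature(store, "tx1", "SO:0000149", "Toyia exempli",
                        residues = res)
  expect_equal(id1, id2)
  expect_equal(nrow(store$tables$feature), 1)
  # update in place: new display name, same id
  upsert_feature(store, "tx1", "SO:0000149", "Toyia exempli",
                 residues = res, display_name = "renamed")
  expect_equal(nrow(store$tables$feature), 1)
  expect_equal(store$tables$feature$display_name, "renamed")
})

test_that("dangling references and invariant violations are rejected", {
  store <- tiny_store(2)
  expect_error(add_relationship(store, "isotig001", "part_of", "nosuch"),
               "unknown feature")
  expect_error(add_relationship(store, "isotig001", "part_of", "isotig001"),
               "itself")
  expect_error(add_location(store, "isotig001", "isotig002", 50, 200),
               "exceeds")
  expect_error(add_location(store, "isotig001", "isotig002", -1, 10),
               "invalid")
  expect_error(add_allele(store, 999L, "nosuch", "A/A"), "unknown marker")
})

test_that("delete cascades to all dependents and reports the removed count", {
  store <- tiny_store(2)
  add_term_annotation(store, "isotig001", "GO:0000001")
  add_term_annotation(store, "isotig001", "GO:0000002")
  upsert_feature(store, "m1", "SO:0000234", "Toyia exempli")
  add_location(store, "m1", "isotig001", 0, 50)
  # transcript + 2 annotations + 1 location (of the child feature on it)
  expect_equal(delete_entity(store, "feature", "isotig001"), 4L)
  expect_equal(nrow(store$tables$term_annotation), 0)
  expect_equal(nrow(store$tables$featureloc), 0)
  expect_error(delete_entity(store, "feature", "isotig001"), "unknown")

  add_genotype(store, "lineA",
               tibble::tibble(term_id = "HAO:1", value = "x"))
  upsert_feature(store, "snpf", "SO:0000694", "Toyia exempli")
  mid <- add_marker(store, "snpf", "SNP", ref_allele = "A", alt_alleles = "G")
  add_allele(store, mid, "lineA", "A/G")
  # genotype + 1 attribute + 1 allele
  expect_equal(delete_entity(store, "genotype", "lineA"), 3L)
  expect_equal(nrow(store$tables$allele), 0)
})

test_that("backup/restore round-trips tables, ontologies and query results", {
  empty <- init_store(tempfile(fileext = ".txdb"))
  dump <- backup(empty)
  expect_equal(nrow(restore(dump)$tables$feature), 0)

  fx <- loaded_toy_store()
  store <- fx$store
  dump <- backup(store)
  s2 <- restore(dump)
  for (tb in names(store$tables)) {
    expect_equal(nrow(s2$tables[[tb]]), nrow(store$tables[[tb]]), info = tb)
  }
  expect_equal(sort(names(s2$ontologies)), sort(names(store$ontologies)))
  expect_equal(tibble::as_tibble(search_by_name(s2, "%")),
               tibble::as_tibble(search_by_name(store, "%")))
  g1 <- get_ontology(store, "TGO"); g2 <- get_ontology(s2, "TGO")
  expect_equal(g2$terms[names(g2$terms) != "synonyms"],
               g1$terms[names(g1$terms) != "synonyms"])
  expect_equal(ancestors(g2, fx$manifest$focus_term),
               ancestors(g1, fx$manifest$focus_term))

  # truncated dump: rejected, target untouched
  target <- tempfile(fileext = ".txdb")
  expect_error(restore(dump[-length(dump)], path = target), "truncated")
  expect_false(file.exists(target))
  expect_error(restore(c("not-a-dump", dump[-1])), "version")
})

test_that("audit log records mutations append-only", {
  store <- tiny_store(1)
  n0 <- nrow(store$tables$audit_log)
  add_term_annotation(store, "isotig001", "GO:0000001")
  delete_entity(store, "feature", "isotig001")
  log <- store$tables$audit_log
  expect_gt(nrow(log), n0)
  expect_true(any(log$action == "delete"))
  expect_equal(log$audit_id, sort(log$audit_id))
})

test_that("glance and tidy summarize the store", {
  fx <- loaded_toy_store()
  g <- glance(fx$store)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_experiments, 3L)
  td <- tidy(fx$store)
  expect_true(all(c("module", "core", "table", "n_rows") %in% names(td)))
  expect_equal(td$n_rows[td$table == "feature"], nrow(fx$store$tables$feature))
})
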