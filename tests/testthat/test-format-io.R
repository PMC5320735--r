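# bulk loaders and exporters; every loader writes through the typed store ops

test_that("FASTA loading tokenizes headers, skips duplicates and empties", {
  store <- tiny_store(0)
  path <- withr::local_tempfile(lines = c(
    ">isotig001 len=500", "ACGTACGT",
    ">isotig002", "GGGG", "CCCC",
    ">isotig003 something else", "TTTT",
    ">isotig001 len=500", "ACGTACGT",
    ">isotig004", ""))
  rep <- load_fasta(store, path, "SO:0000149", "Toyia exempli")
  expect_equal(rep$records_read, 5L)
  expect_equal(rep$records_loaded, 3L)
  expect_equal(rep$records_skipped, 2L)
  expect_equal(rep$records_read, rep$records_loaded + rep$records_skipped)
  expect_equal(nrow(rep$warnings), 2)
  feats <- store$tables$feature
  expect_setequal(feats$unique_name, c("isotig001", "isotig002", "isotig003"))
  expect_equal(feats$seqlen[feats$unique_name == "isotig002"], 8L)
  # multi-line record concatenated, case preserved verbatim
  expect_equal(feats$residues[feats$unique_name == "isotig002"], "GGGGCCCC")

  # loader idempotence: same file twice = same store state
  before <- feats
  load_fasta(store, path, "SO:0000149", "Toyia exempli")
  expect_equal(store$tables$feature, before)
})

test_that("feature lists create residue-less features", {
  store <- tiny_store(0)
  path <- withr::local_tempfile(lines = c("g1", "g2", "", "g3", "g2", "g4", "g5"))
  rep <- load_feature_list(store, path, "SO:0000704", "Toyia exempli")
  expect_equal(rep$records_loaded, 5L)
  expect_equal(rep$records_skipped, 1L)
  expect_true(all(is.na(store$tables$feature$seqlen)))

  empty <- withr::local_tempfile(lines = character())
  rep2 <- load_feature_list(store, empty, "SO:0000704", "Toyia exempli")
  expect_equal(rep2$records_read, 0L)
  expect_equal(nrow(rep2$warnings), 0)
})

test_that("GFF3 converts coordinates to interbase, resolves forward Parents, keeps phase", {
  store <- tiny_store(1, len = 300)
  path <- withr::local_tempfile(lines = c(
    "##gff-version 3",
    # Parent m1 is defined only on the NEXT line: the two-pass contract
    "isotig001\ttoy\texon\t1\t100\t.\t+\t.\tID=e1;Parent=m1",
    "isotig001\ttoy\tmRNA\t1\t250\t.\t+\t.\tID=m1",
    "isotig001\ttoy\tCDS\t31\t180\t.\t-\t2\tID=c1;Parent=m1",
    "unknownseq\ttoy\texon\t1\t10\t.\t+\t.\tID=e9",
    "isotig001\ttoy\texon\t50\t20\t.\t+\t.\tID=bad"))
  rep <- load_gff3(store, path)
  expect_equal(rep$records_read, 5L)
  expect_equal(rep$records_loaded, 3L)
  expect_equal(rep$records_skipped, 2L)
  loc <- store$tables$featureloc
  feats <- store$tables$feature
  eloc <- loc[loc$feature_id == feats$feature_id[feats$unique_name == "e1"], ]
  expect_equal(c(eloc$fmin, eloc$fmax, eloc$strand), c(0L, 100L, 1L))
  cloc <- loc[loc$feature_id == feats$feature_id[feats$unique_name == "c1"], ]
  expect_equal(c(cloc$fmin, cloc$fmax, cloc$strand, cloc$phase),
               c(30L, 180L, -1L, 2L))
  rel <- store$tables$feature_relationship
  e1 <- feats$feature_id[feats$unique_name == "e1"]
  m1 <- feats$feature_id[feats$unique_name == "m1"]
  expect_true(any(rel$subject_id == e1 & rel$predicate == "part_of" &
                    rel$object_id == m1))
  # display coordinates round-trip back to 1-based inclusive
  srep <- sequence_report(store, "isotig001")
  sa <- srep$sections$structural_annotation
  expect_equal(sa$start[sa$unique_name == "e1"], 1L)
  expect_equal(sa$end[sa$unique_name == "e1"], 100L)
  expect_equal(sa$start[sa$unique_name == "c1"], 31L)
  expect_equal(sa$end[sa$unique_name == "c1"], 180L)
})

test_that("BLAST XML loads one record per HSP with identity percentage", {
  store <- tiny_store(1, len = 300)
  xml <- c("<?xml version=\"1.0\"?>", "<BlastOutput>",
           "<BlastOutput_program>blastx</BlastOutput_program>",
           "<BlastOutput_version>BLAST 2.12.0+</BlastOutput_version>",
           "<BlastOutput_db>nr</BlastOutput_db>",
           "<BlastOutput_iterations>",
           "<Iteration><Iteration_query-def>isotig001 len=300</Iteration_query-def>",
           "<Iteration_hits><Hit>",
           "<Hit_accession>A1</Hit_accession><Hit_def>kinase one</Hit_def>",
           "<Hit_hsps>",
           "<Hsp><Hsp_bit-score>100</Hsp_bit-score><Hsp_evalue>1e-30</Hsp_evalue>",
           "<Hsp_query-from>1</Hsp_query-from><Hsp_query-to>100</Hsp_query-to>",
           "<Hsp_identity>90</Hsp_identity><Hsp_align-len>100</Hsp_align-len></Hsp>",
           "<Hsp><Hsp_bit-score>50</Hsp_bit-score><Hsp_evalue>1e-10</Hsp_evalue>",
           "<Hsp_query-from>101</Hsp_query-from><Hsp_query-to>200</Hsp_query-to>",
           "<Hsp_identity>45</Hsp_identity><Hsp_align-len>90</Hsp_align-len></Hsp>",
           "</HITHSPS></Hit>",
           "<Hit><Hit_accession>A2</Hit_accession><Hit_def>other</Hit_def>",
           "<Hit_hsps><Hsp><Hsp_bit-score>30</Hsp_bit-score><Hsp_evalue>0.001</Hsp_evalue>",
           "<Hsp_query-from>5</Hsp_query-from><Hsp_query-to>50</Hsp_query-to>",
           "<Hsp_identity>30</Hsp_identity><Hsp_align-len>46</Hsp_align-len></Hsp></HITHSPS>",
           "</Hit></Iteration_hits></Iteration>",
           "<Iteration><Iteration_query-def>unknownseq</Iteration_query-def>",
           "<Iteration_hits><Hit><Hit_accession>A3</Hit_accession><Hit_def>x</Hit_def>",
           "<Hit_hsps><Hsp><Hsp_bit-score>10</Hsp_bit-score><Hsp_evalue>1</Hsp_evalue>",
           "<Hsp_query-from>1</Hsp_query-from><Hsp_query-to>10</Hsp_query-to>",
           "<Hsp_identity>9</Hsp_identity><Hsp_align-len>10</Hsp_align-len></Hsp></HITHSPS>",
           "</Hit></Iteration_hits></Iteration>",
           "</BlastOutput_iterations></BlastOutput>")
  xml <- gsub("HITHSPS", "Hit_hsps", xml)
  path <- withr::local_tempfile(lines = xml)
  rep <- load_blast_xml(store, path)
  expect_equal(rep$records_read, 4L)    # 3 HSPs for isotig001 + 1 unknown
  expect_equal(rep$records_loaded, 3L)  # per-HSP rule
  expect_equal(rep$records_skipped, 1L)
  expect_match(rep$warnings$message, "unknownseq")
  hits <- store$tables$blast_hit
  expect_equal(nrow(hits), 3)
  expect_equal(hits$identity_pct[hits$bit_score == 100], 90)
  # interbase conversion of query coordinates
  expect_equal(hits$query_start[hits$bit_score == 100], 0L)
  expect_equal(hits$query_end[hits$bit_score == 100], 100L)

  bad <- withr::local_tempfile(lines = "<BlastOutput><unclosed>")
  expect_error(load_blast_xml(store, bad))
})

test_that("ANNOT rows store annotations and skip unknowns with line numbers", {
  store <- tiny_store(2)
  load_ontology(store, chain_graph(), name = "T")
  path <- withr::local_tempfile(lines = c(
    "isotig001\tT:2",
    "isotig001\tT:9",     # unknown term in a loaded prefix
    "nosuch\tT:1",
    "isotig002\tEC:1.1.1.1",  # non-ontology CURIE accepted
    "isotig001\tT:2"))     # duplicate -> idempotent
  rep <- load_annot(store, path)
  expect_equal(rep$records_read, 5L)
  expect_equal(rep$records_loaded, 3L)
  expect_equal(rep$warnings$line, c(2L, 3L))
  ann <- store$tables$term_annotation
  expect_equal(nrow(ann), 2)    # duplicate collapsed
  expect_setequal(ann$term_id, c("T:2", "EC:1.1.1.1"))
})

test_that("InterProScan rows create located domain features and mapped annotations", {
  store <- tiny_store(2, len = 200)
  map <- tibble::tibble(external_id = "IPR000001", term_id = "GO:0008150")
  path <- withr::local_tempfile(lines = c(
    paste("isotig001", "md5", "200", "Pfam", "PF00001", "d", "10", "50",
          "1e-5", "T", "01-01-2020", "IPR000001", "desc", "-", sep = "\t"),
    paste("isotig002", "md5", "200", "Pfam", "PF00002", "d", "20", "60",
          "1e-5", "T", "01-01-2020", "IPR999999", "desc", "-", sep = "\t")))
  rep <- load_interproscan(store, path, map)
  expect_equal(rep$records_loaded, 2L)
  expect_match(rep$warnings$message, "IPR999999", all = FALSE)
  feats <- store$tables$feature
  dom <- feats[feats$so_type == "SO:0000417", ]
  expect_equal(nrow(dom), 2)
  loc <- store$tables$featureloc
  d1 <- loc[loc$feature_id == dom$feature_id[grepl("PF00001", dom$unique_name)], ]
  expect_equal(c(d1$fmin, d1$fmax), c(9L, 50L))   # 1-based 10..50 -> interbase
  ann <- store$tables$term_annotation
  expect_equal(ann$term_id, "GO:0008150")
  expect_equal(ann$source, "dbxref-mapped")
})

test_that("VCF markers locate on transcripts and translate genotype calls", {
  store <- tiny_store(1, len = 300)
  res <- store$tables$feature$residues[1]
  ref100 <- substr(res, 100, 100)
  alt <- setdiff(c("A", "C", "G", "T"), ref100)[1]
  add_genotype(store, "lineA"); add_genotype(store, "lineB")
  path <- withr::local_tempfile(lines = c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tlineA\tlineB",
    sprintf("isotig001\t100\tsnp1\t%s\t%s\t.\tPASS\t.\tGT\t1/1\t./.",
            ref100, alt),
    sprintf("nochrom\t5\tsnp2\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1")))
  rep <- load_vcf_markers(store, path, "SNP")
  expect_equal(rep$records_read, 2L)
  expect_equal(rep$records_loaded, 1L)
  expect_match(rep$warnings$message, "nochrom", all = FALSE)
  loc <- store$tables$featureloc
  expect_equal(c(loc$fmin, loc$fmax), c(99L, 100L))
  al <- store$tables$allele
  expect_equal(nrow(al), 1)           # ./., nothing stored for lineB
  expect_equal(al$value, paste(alt, alt, sep = "/"))

  # SSR with INFO motif
  tract_ref <- substr(res, 10, 21)
  ssr <- withr::local_tempfile(lines = c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MOTIF,Number=1,Type=String,Description=\"m\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tlineA\tlineB",
    sprintf("isotig001\t10\tssr1\t%s\tAGAGAGAGAG\t.\tPASS\tMOTIF=AG\tGT\t0/0\t1/1",
            tract_ref)))
  rep2 <- load_vcf_markers(store, ssr, "SSR")
  expect_equal(rep2$records_loaded, 1L)
  mk <- store$tables$marker
  expect_equal(mk$motif[mk$marker_type == "SSR"], "AG")
})

test_that("association tables dispatch per kind and auto-skip headers", {
  fx <- loaded_toy_store()
  store <- restore(backup(fx$store))   # throwaway copy
  lib <- store$tables$seq_library$name[1]
  path <- withr::local_tempfile(lines = c(
    "feature\tlibrary\tvalue",
    paste("isotig001", lib, "154", sep = "\t"),
    paste("nosuch", lib, "3", sep = "\t")))
  rep <- load_association_table(store, path, "feature_library")
  expect_equal(rep$records_read, 2L)   # header not counted
  expect_equal(rep$records_loaded, 1L)
  ev <- store$tables$expression_value
  fid <- store$tables$feature$feature_id[
    store$tables$feature$unique_name == "isotig001"]
  lid <- store$tables$seq_library$library_id[1]
  expect_equal(ev$value[ev$feature_id == fid & ev$library_id == lid &
                          ev$measure == "raw_count"], 154)

  ffpath <- withr::local_tempfile(
    lines = "isotig001\tderives_from\tisotig002")
  rep2 <- load_association_table(store, ffpath, "feature_feature")
  expect_equal(rep2$records_loaded, 1L)
  rel <- store$tables$feature_relationship
  expect_true(any(rel$predicate == "derives_from"))

  cvpath <- withr::local_tempfile(
    lines = paste("isotig001", fx$manifest$focus_term, sep = "\t"))
  rep3 <- load_association_table(store, cvpath, "feature_cv")
  expect_equal(rep3$records_loaded, 1L)
})

test_that("FASTA and ANNOT exports are exact inverses of their loaders", {
  fx <- loaded_toy_store()
  store <- fx$store
  # FASTA round trip: residues byte-identical
  out <- tempfile(fileext = ".fasta")
  export_fasta(store, path = out)
  s2 <- tiny_store(0)
  load_fasta(s2, out, "SO:0000149", "Toyia exempli")
  orig <- store$tables$feature[!is.na(store$tables$feature$residues), ]
  got <- s2$tables$feature
  expect_equal(nrow(got), nrow(orig))
  expect_equal(
    stats::setNames(got$residues, got$unique_name)[order(got$unique_name)],
    stats::setNames(orig$residues, orig$unique_name)[order(orig$unique_name)])

  # ANNOT round trip: identical annotation set
  apath <- tempfile(fileext = ".annot")
  export_annot(store, path = apath)
  load_ontology(s2, file.path(fx$dir, "ontology.obo"), name = "TGO")
  rep <- load_annot(s2, apath)
  expect_equal(rep$records_skipped, 0L)
  pairs <- function(st) {
    ann <- st$tables$term_annotation
    fn <- st$tables$feature$unique_name[match(ann$feature_id,
                                              st$tables$feature$feature_id)]
    sort(paste(fn, ann$term_id))
  }
  expect_equal(unique(pairs(s2)), unique(pairs(store)))

  # CSV export quotes fields containing delimiters
  q <- tibble::tibble(unique_name = "x", description = "a, b")
  expect_match(export_table(q), "\"a, b\"")
  # residue-less request warns and skips
  s3 <- tiny_store(1)
  upsert_feature(s3, "genes1", "SO:0000704", "Toyia exempli")
  expect_warning(lines <- export_fasta(s3, c("isotig001", "genes1")),
                 "without residues")
  expect_equal(sum(grepl("^>", lines)), 1)
})
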