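#' Synthetic transcriptome fixtures
#'
#' Deterministic generators for a toy ontology and a complete toy de novo
#' transcriptome project in the standard input formats, together with a
#' ground-truth manifest. The project emulates the structure of a Newbler
#' 454 assembly — isotigs (transcript contigs) grouped into isogroups (gene
#' loci without residues) — annotated, marked and measured across a
#' three-condition experimental design with one library per condition.
#' Sequence content is uniform-random nucleotide text with planted SSR
#' motifs: structural realism (grouping, markers, replicates, annotation
#' overlap), not biological realism, is the goal. Every expected answer in
#' the manifest is computed by independent brute-force code (set scans and
#' boolean-matrix closure), never by the loaders and queries it is used to
#' test.
#'
#' @name fixtures
NULL

#' Describe a synthetic project
#'
#' The defaults are the study conditions the tutorial walks through: three
#' experiments named `male_larvae`, `male_adult` and `female_adult` with one
#' RNA-seq library each, ten gene loci with 1-3 isoforms, and a handful of
#' SSR and SNP markers.
#'
#' @param seed Integer seed; the same spec and seed give byte-identical
#'   output files.
#' @param n_isogroups Number of gene loci.
#' @param isoforms_per_group Length-2 range of isoforms per locus.
#' @param transcript_length_bp Length-2 range of transcript lengths.
#' @param n_ssr,n_snp Number of transcripts carrying an SSR / a SNP (at most
#'   one of each per transcript).
#' @param n_ontology_terms Size of the toy functional ontology (>= 8 for the
#'   full planted layout).
#' @param diamond_fraction Probability that a random term gets a second
#'   parent (multi-parent "diamond" structure).
#' @param experiments Tibble with `name`, `n_replicates`, `total_reads`,
#'   `condition_terms` (list column of anatomy-ontology CURIEs).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_isogroups = 10L,
                         isoforms_per_group = c(1L, 3L),
                         transcript_length_bp = c(300L, 900L),
                         n_ssr = 8L, n_snp = 10L, n_ontology_terms = 30L,
                         diamond_fraction = 0.3,
                         experiments = NULL) {
  experiments <- experiments %||% tibble::tibble(
    name = c("male_larvae", "male_adult", "female_adult"),
    n_replicates = 1L,
    total_reads = 1000000L,
    condition_terms = list(c("THAO:0000002", "THAO:0000004"),
                           c("THAO:0000003", "THAO:0000004"),
                           c("THAO:0000003", "THAO:0000005")))
  structure(list(seed = as.integer(seed), n_isogroups = as.integer(n_isogroups),
                 isoforms_per_group = as.integer(isoforms_per_group),
                 transcript_length_bp = as.integer(transcript_length_bp),
                 n_ssr = as.integer(n_ssr), n_snp = as.integer(n_snp),
                 n_ontology_terms = as.integer(n_ontology_terms),
                 diamond_fraction = diamond_fraction, experiments = experiments),
            class = "fixture_spec")
}

tgo_id <- function(i) sprintf("TGO:%07d", i)

#' Generate a toy functional ontology in OBO form
#'
#' A rooted DAG with a controlled fraction of multi-parent (diamond) terms, a
#' designated focus term playing the reproductive-development role in
#' replays (with guaranteed children), one obsolete term, and a mix of `is_a`
#' and `part_of` edges. Deterministic under the spec's seed.
#'
#' @param spec A [fixture_spec()].
#' @return Character vector of OBO lines. The focus term id is attached as
#'   the `"focus_term"` attribute.
#' @export
make_toy_ontology <- function(spec) {
  n <- spec$n_ontology_terms
  stopifnot(n >= 1)
  withr::with_seed(spec$seed, {
    parents <- vector("list", n)
    preds <- vector("list", n)
    obsolete <- rep(FALSE, n)
    names_ <- paste("toy biological process", seq_len(n))
    names_[1] <- "biological_process"
    focus <- 1L
    if (n >= 8) {
      parents[[2]] <- 1L; preds[[2]] <- "is_a"
      parents[[3]] <- 1L; preds[[3]] <- "is_a"
      parents[[4]] <- c(2L, 3L); preds[[4]] <- c("is_a", "is_a")   # diamond
      parents[[5]] <- 2L; preds[[5]] <- "is_a"
      focus <- 5L
      names_[5] <- "developmental process involved in reproduction"
      parents[[6]] <- 5L; preds[[6]] <- "is_a"
      parents[[7]] <- 5L; preds[[7]] <- "part_of"
      obsolete[n] <- TRUE
      names_[n] <- "obsolete toy process"
      free <- setdiff(seq_len(n), c(1:7, n))
    } else {
      free <- setdiff(seq_len(n), 1L)
    }
    for (i in free) {
      p <- sample.int(i - 1L, 1L)
      parents[[i]] <- p
      preds[[i]] <- sample(c("is_a", "part_of"), 1L, prob = c(0.8, 0.2))
      if (i >= 3 && stats::runif(1) < spec$diamond_fraction) {
        p2 <- sample(setdiff(seq_len(i - 1L), p), 1L)
        parents[[i]] <- c(parents[[i]], p2)
        preds[[i]] <- c(preds[[i]], "is_a")
      }
    }
    lines <- c("format-version: 1.2", "ontology: tgo", "")
    for (i in seq_len(n)) {
      stanza <- c("[Term]", paste0("id: ", tgo_id(i)),
                  paste0("name: ", names_[i]),
                  "namespace: toy_process")
      if (obsolete[i]) {
        stanza <- c(stanza, "is_obsolete: true")
      } else {
        for (k in seq_along(parents[[i]])) {
          p <- parents[[i]][k]
          stanza <- c(stanza, if (preds[[i]][k] == "is_a") {
            paste0("is_a: ", tgo_id(p), " ! ", names_[p])
          } else {
            paste0("relationship: part_of ", tgo_id(p), " ! ", names_[p])
          })
        }
      }
      lines <- c(lines, stanza, "")
    }
    attr(lines, "focus_term") <- tgo_id(focus)
    lines
  })
}

# fixed toy Sequence Ontology slice covering the feature types the loaders use
make_toy_so <- function() {
  nm <- names(TX_SO_TYPES)
  root <- TX_SO_TYPES[["sequence_feature"]]
  lines <- c("format-version: 1.2", "ontology: so", "")
  for (i in seq_along(nm)) {
    stanza <- c("[Term]", paste0("id: ", TX_SO_TYPES[[i]]),
                paste0("name: ", nm[i]), "namespace: sequence")
    if (TX_SO_TYPES[[i]] != root) {
      stanza <- c(stanza, paste0("is_a: ", root, " ! sequence_feature"))
    }
    lines <- c(lines, stanza, "")
  }
  lines
}

# fixed toy anatomy/condition ontology used to describe experiments
make_toy_hao <- function() {
  terms <- c("THAO:0000001" = "organism attribute",
             "THAO:0000002" = "larval stage", "THAO:0000003" = "adult stage",
             "THAO:0000004" = "male", "THAO:0000005" = "female")
  lines <- c("format-version: 1.2", "ontology: thao", "")
  for (i in seq_along(terms)) {
    stanza <- c("[Term]", paste0("id: ", names(terms)[i]),
                paste0("name: ", terms[[i]]), "namespace: toy_anatomy")
    if (i > 1) stanza <- c(stanza, "is_a: THAO:0000001 ! organism attribute")
    lines <- c(lines, stanza, "")
  }
  lines
}

# independent closure oracle: boolean-matrix transitive closure over the
# closure-predicate edges of an edge list (subject, object) on ids 1..n
brute_closure <- function(n, edges) {
  reach <- matrix(FALSE, n, n)
  if (nrow(edges)) reach[cbind(edges$subject, edges$object)] <- TRUE
  repeat {
    nxt <- reach | ((reach %*% reach) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate a complete toy project bundle
#'
#' Writes mutually consistent files in every supported input format (FASTA
#' isotigs, isogroup list, relationships table, GFF3, BLAST XML, ANNOT,
#' InterProScan TSV with a dbxref map, SNP and SSR VCFs, genotype /
#' experiment / library / expression tables, plus the three toy ontologies)
#' and a `ground_truth.json` manifest whose expected answer sets are computed
#' at generation time by brute force.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths) and `manifest`
#'   (the ground-truth list, also written as JSON).
#' @export
make_toy_project <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_tx_max <- spec$n_isogroups * spec$isoforms_per_group[2]
  if (spec$n_ssr > n_tx_max || spec$n_snp > n_tx_max) {
    stop("infeasible spec: more markers than transcripts can carry",
         call. = FALSE)
  }
  obo <- make_toy_ontology(spec)
  focus <- attr(obo, "focus_term")

  withr::with_seed(spec$seed + 1L, {
    # --- structure: isogroups and isotigs -----------------------------------
    k <- sample(seq(spec$isoforms_per_group[1], spec$isoforms_per_group[2]),
                spec$n_isogroups, replace = TRUE)
    groups <- sprintf("isogroup%02d", seq_len(spec$n_isogroups))
    tigs <- sprintf("isotig%03d", seq_len(sum(k)))
    tig_group <- rep(groups, k)
    if (spec$n_ssr > length(tigs) || spec$n_snp > length(tigs)) {
      stop("infeasible spec: more markers than transcripts", call. = FALSE)
    }
    lens <- sample(seq(spec$transcript_length_bp[1],
                       spec$transcript_length_bp[2]), length(tigs),
                   replace = TRUE)
    seqs <- vapply(lens, rand_dna, character(1))

    # --- markers ------------------------------------------------------------
    ssr_tigs <- sort(sample(tigs, spec$n_ssr))
    ssr_motif <- sample(c("AG", "AC", "AT", "AAG", "ATC"), spec$n_ssr,
                        replace = TRUE)
    ssr_pos <- integer(spec$n_ssr)
    for (j in seq_len(spec$n_ssr)) {
      i <- match(ssr_tigs[j], tigs)
      tract <- strrep(ssr_motif[j], 6L)
      pos <- sample.int(lens[i] - nchar(tract) - 1L, 1L)
      seqs[i] <- paste0(substr(seqs[i], 1, pos - 1), tract,
                        substr(seqs[i], pos + nchar(tract), lens[i]))
      ssr_pos[j] <- pos
    }
    snp_tigs <- sort(sample(tigs, spec$n_snp))
    snp_pos <- vapply(snp_tigs, function(t) sample.int(lens[match(t, tigs)], 1L),
                      integer(1))

    # --- annotations (master table, then split across files) ----------------
    n_terms <- spec$n_ontology_terms
    tgo_edges <- obo_closure_edges(obo)
    reach <- brute_closure(n_terms, tgo_edges)
    focus_i <- as.integer(sub("TGO:0*", "", focus))
    under_focus_terms <- c(focus_i, which(reach[, focus_i]))
    obsolete_i <- if (n_terms >= 8) n_terms else integer()
    assignable <- setdiff(seq_len(n_terms), obsolete_i)

    master <- list()
    for (i in seq_along(tigs)) {
      terms <- sample(assignable, sample(1:3, 1L))
      master[[i]] <- tibble::tibble(feature = tigs[i], term = terms)
    }
    master <- dplyr::bind_rows(master)
    # plant guarantees: multi-annotation under the root, and an SSR/focus overlap
    if (n_terms >= 8) {
      master <- dplyr::bind_rows(master, tibble::tibble(
        feature = tigs[1], term = c(2L, 3L)))
      focus_ssr <- ssr_tigs[seq_len(min(2L, length(ssr_tigs)))]
      master <- dplyr::bind_rows(master, tibble::tibble(
        feature = focus_ssr,
        term = sample(under_focus_terms, length(focus_ssr), replace = TRUE)))
    }
    master <- dplyr::distinct(master)

    # route ~3 transcripts' extra annotation through InterProScan
    ipr_tigs <- sort(sample(tigs, min(3L, length(tigs))))
    ipr_acc <- c("IPR000001", "IPR000002", "IPR000003", "IPR000004")
    ipr_map <- tibble::tibble(external_id = ipr_acc[1:3],
                              term_id = tgo_id(sample(assignable, 3L)))
    ipr_rows <- tibble::tibble(
      feature = ipr_tigs,
      signature = sprintf("PF%05d", seq_along(ipr_tigs)),
      start = 10L + seq_along(ipr_tigs),
      end = 50L + seq_along(ipr_tigs),
      interpro = ipr_acc[seq_along(ipr_tigs)],
      go = c(tgo_id(sample(assignable, 1L)),
             rep("-", length(ipr_tigs) - 1L)))
    ipr_terms <- dplyr::bind_rows(
      tibble::tibble(
        feature = ipr_rows$feature,
        term = as.integer(sub("TGO:0*", "",
                              ipr_map$term_id[match(ipr_rows$interpro,
                                                    ipr_map$external_id)]))),
      tibble::tibble(feature = ipr_rows$feature[ipr_rows$go != "-"],
                     term = as.integer(sub("TGO:0*", "",
                                           ipr_rows$go[ipr_rows$go != "-"]))))
    ipr_terms <- ipr_terms[!is.na(ipr_terms$term), , drop = FALSE]
    all_ann <- dplyr::distinct(dplyr::bind_rows(master, ipr_terms))

    # --- ground truth by brute force ----------------------------------------
    ann_sets <- split(all_ann$term, all_ann$feature)
    under <- function(term_i) {
      names(ann_sets)[vapply(ann_sets, function(s) {
        any(s == term_i) || any(reach[s, term_i])
      }, logical(1))]
    }
    under_focus <- sort(under(focus_i))
    ssr_under_focus <- sort(intersect(ssr_tigs, under_focus))
    root_children <- sort(tgo_edges$subject[tgo_edges$object == 1L &
                                              !tgo_edges$subject %in% obsolete_i])
    root_child_counts <- stats::setNames(
      vapply(root_children, function(ch) length(under(ch)), integer(1)),
      tgo_id(root_children))

    # --- expression design ---------------------------------------------------
    design <- spec$experiments
    libs <- list()
    for (e in seq_len(nrow(design))) {
      for (r in seq_len(design$n_replicates[e])) {
        libs[[length(libs) + 1L]] <- tibble::tibble(
          experiment = design$name[e], name = sprintf("lib_%s_%d",
                                                      design$name[e], r),
          replicate_index = r, total_reads = design$total_reads[e])
      }
    }
    libs <- dplyr::bind_rows(libs)
    larvae_exp <- design$name[grepl("larva", design$name)][1]
    if (is.na(larvae_exp)) larvae_exp <- design$name[1]
    planted_group <- groups[which.max(k)]
    planted_tigs <- tigs[tig_group == planted_group]
    expr <- list()
    for (j in seq_len(nrow(libs))) {
      base <- stats::rpois(length(tigs), 50)
      planted <- tigs %in% planted_tigs
      cnt <- ifelse(planted,
                    if (libs$experiment[j] == larvae_exp)
                      1500L + stats::rpois(length(tigs), 100) else
                        stats::rpois(length(tigs), 3),
                    base)
      expr[[j]] <- tibble::tibble(feature = tigs, library = libs$name[j],
                                  count = as.integer(cnt))
    }
    expr <- dplyr::bind_rows(expr)
    expr_truth <- expr |>
      dplyr::left_join(libs[c("name", "experiment")],
                       by = c(library = "name")) |>
      dplyr::group_by(.data$feature, .data$experiment) |>
      dplyr::summarise(
        mean = mean(.data$count),
        sd = if (dplyr::n() > 1) stats::sd(.data$count) else 0,
        n = dplyr::n(), .groups = "drop")

    # --- BLAST hits ----------------------------------------------------------
    blast_tigs <- sort(sample(tigs, min(5L, length(tigs))))
    kinase_tigs <- blast_tigs[seq_len(min(2L, length(blast_tigs)))]
    blast_desc <- ifelse(blast_tigs %in% kinase_tigs,
                         "serine/threonine protein kinase",
                         "hypothetical protein")

    # --- write the bundle -----------------------------------------------------
    p <- function(f) file.path(dir, f)
    paths <- c(ontology = p("ontology.obo"), so = p("so.obo"), hao = p("hao.obo"),
               fasta = p("isotigs.fasta"), isogroups = p("isogroups.txt"),
               relationships = p("relationships.tsv"), gff3 = p("structure.gff3"),
               annot = p("annotations.annot"), blast = p("blast.xml"),
               interpro = p("interpro.tsv"), dbxref = p("ipr2go.map"),
               snp_vcf = p("snps.vcf"), ssr_vcf = p("ssrs.vcf"),
               genotypes = p("genotypes.tsv"), experiments = p("experiments.tsv"),
               libraries = p("libraries.tsv"), expression = p("expression.tsv"),
               manifest = p("ground_truth.json"))

    writeLines(obo, paths["ontology"])
    writeLines(make_toy_so(), paths["so"])
    writeLines(make_toy_hao(), paths["hao"])
    writeLines(unlist(lapply(seq_along(tigs), function(i) {
      c(sprintf(">%s len=%d gene=%s", tigs[i], lens[i], tig_group[i]), seqs[i])
    })), paths["fasta"])
    writeLines(groups, paths["isogroups"])
    writeLines(paste(tigs, "part_of", tig_group, sep = "\t"),
               paths["relationships"])
    writeLines(make_fixture_gff3(tigs, lens), paths["gff3"])
    writeLines(paste(master$feature, tgo_id(master$term), sep = "\t"),
               paths["annot"])
    writeLines(make_fixture_blast_xml(blast_tigs, blast_desc, lens[match(blast_tigs, tigs)]),
               paths["blast"])
    writeLines(sprintf("%s\tmd5\t%d\tPfam\t%s\tdomain\t%d\t%d\t1e-10\tT\t01-01-2020\t%s\tdesc\t%s",
                       ipr_rows$feature, lens[match(ipr_rows$feature, tigs)],
                       ipr_rows$signature, ipr_rows$start, ipr_rows$end,
                       ipr_rows$interpro, ipr_rows$go), paths["interpro"])
    writeLines(c("! toy interpro2go mapping",
                 paste(ipr_map$external_id, ipr_map$term_id, sep = "\t")),
               paths["dbxref"])
    writeLines(make_fixture_vcf(
      tigs, seqs, snp_tigs, snp_pos, type = "SNP"), paths["snp_vcf"])
    writeLines(make_fixture_vcf(
      tigs, seqs, ssr_tigs, ssr_pos, type = "SSR", motif = ssr_motif),
      paths["ssr_vcf"])
    writeLines(c("name\tterm_id\tvalue",
                 "lineA\tTHAO:0000004\t", "lineB\tTHAO:0000005\t"),
               paths["genotypes"])
    writeLines(c("name\tcondition_terms",
                 paste(design$name,
                       vapply(design$condition_terms, paste, character(1),
                              collapse = ","), sep = "\t")),
               paths["experiments"])
    writeLines(c("experiment\tname\treplicate_index\ttotal_reads",
                 paste(libs$experiment, libs$name, libs$replicate_index,
                       libs$total_reads, sep = "\t")), paths["libraries"])
    writeLines(c("feature\tlibrary\tvalue",
                 paste(expr$feature, expr$library, expr$count, sep = "\t")),
               paths["expression"])

    manifest <- list(
      seed = spec$seed,
      focus_term = focus,
      isotigs = tigs, isogroups = groups,
      isotig_to_isogroup = stats::setNames(as.list(tig_group), tigs),
      transcript_lengths = stats::setNames(as.list(lens), tigs),
      ssr_transcripts = ssr_tigs, snp_transcripts = as.character(snp_tigs),
      under_focus = under_focus, ssr_under_focus = ssr_under_focus,
      root_child_counts = as.list(root_child_counts),
      root_total = length(names(ann_sets)),
      annotations = stats::setNames(
        lapply(split(all_ann$term, all_ann$feature), function(x) tgo_id(sort(x))),
        names(split(all_ann$term, all_ann$feature))),
      kinase_features = as.character(kinase_tigs),
      planted_group = planted_group, planted_isotigs = planted_tigs,
      larvae_experiment = larvae_exp,
      experiments = design$name,
      libraries_per_experiment = stats::setNames(
        as.list(as.integer(design$n_replicates)), design$name),
      expression_truth = expr_truth)
    jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(list(paths = paths, manifest = manifest))
  })
}

# closure-predicate edge list (integer indices) straight from OBO text,
# independent of parse_obo
obo_closure_edges <- function(obo_lines) {
  cur <- NA_integer_
  subj <- integer(); obj <- integer()
  for (ln in obo_lines) {
    if (grepl("^id: TGO:", ln)) cur <- as.integer(sub("^id: TGO:0*", "", ln))
    if (grepl("^is_a: TGO:", ln)) {
      subj <- c(subj, cur)
      obj <- c(obj, as.integer(sub("^is_a: TGO:0*(\\d+).*$", "\\1", ln)))
    }
    if (grepl("^relationship: part_of TGO:", ln)) {
      subj <- c(subj, cur)
      obj <- c(obj, as.integer(sub("^relationship: part_of TGO:0*(\\d+).*$",
                                   "\\1", ln)))
    }
  }
  tibble::tibble(subject = subj, object = obj)
}

make_fixture_gff3 <- function(tigs, lens) {
  rows <- unlist(lapply(seq_along(tigs), function(i) {
    mrna <- paste0("mrna_", tigs[i])
    cds_start <- max(1L, lens[i] %/% 4L)
    cds_end <- min(lens[i], cds_start + lens[i] %/% 2L)
    c(sprintf("%s\ttoy\tmRNA\t1\t%d\t.\t+\t.\tID=%s", tigs[i], lens[i], mrna),
      sprintf("%s\ttoy\texon\t1\t%d\t.\t+\t.\tID=exon_%s;Parent=%s",
              tigs[i], lens[i], tigs[i], mrna),
      sprintf("%s\ttoy\tCDS\t%d\t%d\t.\t+\t0\tID=cds_%s;Parent=%s",
              tigs[i], cds_start, cds_end, tigs[i], mrna))
  }))
  c("##gff-version 3", rows)
}

make_fixture_blast_xml <- function(tigs, descs, lens) {
  iters <- unlist(lapply(seq_along(tigs), function(i) {
    c("<Iteration>",
      sprintf("  <Iteration_query-def>%s len=%d</Iteration_query-def>",
              tigs[i], lens[i]),
      "  <Iteration_hits>",
      "    <Hit>",
      sprintf("      <Hit_accession>ACC%05d</Hit_accession>", i),
      sprintf("      <Hit_def>%s [Toyia exempli]</Hit_def>", descs[i]),
      "      <Hit_hsps>",
      "        <Hsp>",
      sprintf("          <Hsp_bit-score>%.1f</Hsp_bit-score>", 200 + i),
      sprintf("          <Hsp_evalue>%g</Hsp_evalue>", 10^(-20 - i)),
      "          <Hsp_query-from>1</Hsp_query-from>",
      sprintf("          <Hsp_query-to>%d</Hsp_query-to>", min(150L, lens[i])),
      "          <Hsp_identity>120</Hsp_identity>",
      "          <Hsp_align-len>150</Hsp_align-len>",
      "        </Hsp>",
      "      </Hit_hsps>",
      "    </Hit>",
      "  </Iteration_hits>",
      "</Iteration>")
  }))
  c("<?xml version=\"1.0\"?>",
    "<BlastOutput>",
    "  <BlastOutput_program>blastx</BlastOutput_program>",
    "  <BlastOutput_version>BLAST 2.12.0+</BlastOutput_version>",
    "  <BlastOutput_db>nr</BlastOutput_db>",
    "  <BlastOutput_iterations>", iters, "  </BlastOutput_iterations>",
    "</BlastOutput>")
}

make_fixture_vcf <- function(tigs, seqs, m_tigs, m_pos, type, motif = NULL) {
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=MOTIF,Number=1,Type=String,Description=\"SSR motif\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tlineA\tlineB")
  rows <- vapply(seq_along(m_tigs), function(j) {
    i <- match(m_tigs[j], tigs)
    pos <- m_pos[j]
    if (type == "SNP") {
      ref <- substr(seqs[i], pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      gts <- sample(c("0/0", "0/1", "1/1", "./."), 2L, replace = TRUE,
                    prob = c(0.4, 0.25, 0.25, 0.1))
      sprintf("%s\t%d\tsnp_%s\t%s\t%s\t.\tPASS\t.\tGT\t%s\t%s",
              m_tigs[j], pos, m_tigs[j], ref, alt, gts[1], gts[2])
    } else {
      tract <- strrep(motif[j], 6L)
      ref <- substr(seqs[i], pos, pos + nchar(tract) - 1L)
      alt <- strrep(motif[j], 5L)
      sprintf("%s\t%d\tssr_%s\t%s\t%s\t.\tPASS\tMOTIF=%s\tGT\t0/0\t1/1",
              m_tigs[j], pos, m_tigs[j], ref, alt, motif[j])
    }
  }, character(1))
  c(header, rows)
}

#' Load genotypes from a simple table
#'
#' Rows: genotype name, optional ontology term, optional value. A header row
#' is auto-detected.
#'
#' @param store A `tx_store`.
#' @param path TSV file.
#' @return A `tx_load_report`.
#' @export
load_genotypes <- function(store, path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^#", lines))
  if (length(keep) && grepl("^name\\b", lines[[keep[1]]], ignore.case = TRUE)) {
    keep <- keep[-1]
  }
  read <- 0L; loaded <- 0L
  wc <- warn_collector()
  for (i in keep) {
    parts <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]])
    read <- read + 1L
    if (!nzchar(parts[1])) { wc$add(i, "blank genotype name"); next }
    attrs <- if (length(parts) >= 2 && nzchar(parts[2])) {
      tibble::tibble(term_id = parts[2],
                     value = if (length(parts) >= 3 && nzchar(parts[3]))
                       parts[3] else NA_character_)
    } else NULL
    add_genotype(store, parts[1], attrs)
    loaded <- loaded + 1L
  }
  new_load_report(read, loaded, read - loaded, wc$tbl())
}

#' Replay the full tutorial workflow on a toy bundle
#'
#' Runs the complete loading pipeline against a [make_toy_project()] bundle:
#' ontologies, organism, isotigs (FASTA), isogroups (list), relationships,
#' GFF3 structure, ANNOT and InterProScan annotation with the dbxref map,
#' BLAST XML, genotypes, SNP and SSR VCF markers, the experiment/library
#' design, raw-count expression values and their RPKM conversion.
#'
#' @param dir Directory written by [make_toy_project()].
#' @param store_path Where to create the store (default: temporary file).
#' @return The loaded `tx_store`.
#' @export
replay_project <- function(dir, store_path = tempfile(fileext = ".txdb")) {
  p <- function(f) file.path(dir, f)
  store <- init_store(store_path, overwrite = TRUE)
  load_ontology(store, p("ontology.obo"), name = "TGO")
  load_ontology(store, p("so.obo"), name = "SO")
  load_ontology(store, p("hao.obo"), name = "HAO")
  org <- add_organism(store, "Toyia", "exempli")
  load_fasta(store, p("isotigs.fasta"), so_type = TX_SO_TYPES[["contig"]],
             organism = org)
  load_feature_list(store, p("isogroups.txt"), so_type = TX_SO_TYPES[["gene"]],
                    organism = org)
  load_association_table(store, p("relationships.tsv"), kind = "feature_feature")
  load_gff3(store, p("structure.gff3"))
  load_annot(store, p("annotations.annot"))
  load_blast_xml(store, p("blast.xml"))
  load_interproscan(store, p("interpro.tsv"),
                    dbxref_mapping = read_dbxref_map(p("ipr2go.map")))
  load_genotypes(store, p("genotypes.tsv"))
  load_vcf_markers(store, p("snps.vcf"), marker_type = "SNP")
  load_vcf_markers(store, p("ssrs.vcf"), marker_type = "SSR")

  exps <- readr::read_tsv(p("experiments.tsv"), show_col_types = FALSE)
  for (i in seq_len(nrow(exps))) {
    create_experiment(store, exps$name[i],
                      strsplit(exps$condition_terms[i], ",", fixed = TRUE)[[1]])
  }
  libs <- readr::read_tsv(p("libraries.tsv"), show_col_types = FALSE)
  for (i in seq_len(nrow(libs))) {
    add_library(store, libs$experiment[i], libs$name[i],
                libs$replicate_index[i], libs$total_reads[i])
  }
  load_association_table(store, p("expression.tsv"), kind = "feature_library")
  for (nm in libs$name) suppressWarnings(rpkm_for_library(store, nm))
  tx_save(store)
  store
}

#' The case-study combined query
#'
#' "Which transcripts carry at least `min_ssr` SSR marker(s) and are
#' annotated — directly or by inheritance — under the focus term?", composed
#' from the package's own query surface: a `%` name search over transcripts,
#' the marker filter, then intersection with the ontology term search.
#'
#' @param store A loaded `tx_store`.
#' @param focus Focus term CURIE (e.g. the manifest's `focus_term`).
#' @param ontology Ontology name holding the focus term (default `"TGO"`).
#' @param min_ssr Minimum SSR count (default 1).
#' @return A `tx_query` of the matching transcripts.
#' @export
case_study_query <- function(store, focus, ontology = "TGO", min_ssr = 1L) {
  g <- get_ontology(store, ontology)
  all_tx <- search_by_name(store, "%", mode = "like",
                           so_type = TX_SO_TYPES[["contig"]])
  with_ssr <- filter_by_marker(all_tx, store, "SSR", min_count = min_ssr)
  under <- search_by_term(store, g, focus, include_inherited = TRUE)
  rows <- with_ssr[with_ssr$unique_name %in% under$unique_name, , drop = FALSE]
  new_tx_query(tibble::as_tibble(rows),
               sprintf(">=%d SSR and annotated under %s", min_ssr, focus))
}
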