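#' Integrated reports
#'
#' Four report types mirror the application's detail views: the sequence
#' report (six sections: residues, non-positional relationships, structural
#' annotation, functional annotation with the reduced ontology subgraph,
#' BLAST results, expression results), and the marker, experiment and
#' genotype reports. Every report field is re-derived from store queries at
#' call time; displayed coordinates are 1-based inclusive while storage is
#' interbase.
#'
#' @name reports
NULL

relationship_rows <- function(store, fid) {
  rel <- store$tables$feature_relationship
  feats <- store$tables$feature
  rel <- rel[rel$subject_id == fid | rel$object_id == fid, , drop = FALSE]
  tibble::tibble(
    subject = feats$unique_name[match(rel$subject_id, feats$feature_id)],
    predicate = rel$predicate,
    object = feats$unique_name[match(rel$object_id, feats$feature_id)])
}

#' Sequence report for one feature
#'
#' For a feature with residues the report has the six sections; a
#' residue-less feature (e.g. a gene locus known only as a grouping) gets the
#' general report, which has only the relationships section.
#'
#' @param store A `tx_store`.
#' @param feature Feature name or id.
#' @param graph Optional `ontology_graph` for the functional-annotation
#'   subgraph; when `NULL`, the loaded ontology containing the feature's
#'   terms is used if there is one.
#' @return A `tx_sequence_report`: `feature`, `so_type` and a named `sections`
#'   list.
#' @export
sequence_report <- function(store, feature, graph = NULL) {
  fid <- resolve_feature(store, feature)
  feats <- store$tables$feature
  row <- feats[feats$feature_id == fid, , drop = FALSE]

  if (is.na(row$residues)) {
    rep <- list(feature = row$unique_name, so_type = row$so_type,
                sections = list(relationships = relationship_rows(store, fid)))
    class(rep) <- "tx_sequence_report"
    return(rep)
  }

  loc <- store$tables$featureloc
  kids <- loc[loc$srcfeature_id == fid, , drop = FALSE]
  structural <- tibble::tibble(
    unique_name = feats$unique_name[match(kids$feature_id, feats$feature_id)],
    so_type = feats$so_type[match(kids$feature_id, feats$feature_id)],
    start = kids$fmin + 1L,  # display convention: 1-based inclusive
    end = kids$fmax,
    strand = kids$strand,
    phase = kids$phase) |>
    dplyr::arrange(.data$start, .data$unique_name)

  ann <- store$tables$term_annotation
  ann <- ann[ann$feature_id == fid, , drop = FALSE]
  if (is.null(graph) && nrow(ann)) {
    onto <- find_store_term(store, ann$term_id[1])
    if (!is.na(onto)) graph <- store$ontologies[[onto]]
  }
  direct_terms <- sort(unique(ann$term_id))
  functional <- list(
    direct = tibble::tibble(
      term_id = ann$term_id,
      name = if (!is.null(graph))
        graph$terms$name[match(ann$term_id, graph$terms$term_id)] else
          NA_character_,
      source = ann$source) |> dplyr::arrange(.data$term_id),
    inherited = tibble::tibble(term_id = character(), name = character()),
    subgraph = NULL)
  if (!is.null(graph)) {
    in_graph <- direct_terms[direct_terms %in% graph$terms$term_id]
    if (length(in_graph)) {
      inh <- sort(setdiff(unique(unlist(lapply(in_graph, ancestors,
                                               graph = graph))), in_graph))
      functional$inherited <- tibble::tibble(
        term_id = inh, name = graph$terms$name[match(inh, graph$terms$term_id)])
      functional$subgraph <- annotation_subgraph(graph, in_graph)
    }
  }

  hits <- store$tables$blast_hit
  hits <- hits[hits$feature_id == fid, , drop = FALSE]
  blast <- tibble::tibble(
    hit_accession = hits$hit_accession, description = hits$description,
    e_value = hits$e_value, bit_score = hits$bit_score,
    identity_pct = hits$identity_pct,
    query_start = hits$query_start + 1L, query_end = hits$query_end,
    db_name = hits$db_name) |> dplyr::arrange(.data$e_value)

  rep <- list(
    feature = row$unique_name, so_type = row$so_type,
    sections = list(
      residues = list(seqlen = row$seqlen, sequence = row$residues),
      relationships = relationship_rows(store, fid),
      structural_annotation = structural,
      functional_annotation = functional,
      blast_results = blast,
      expression_results = expression_profile(store, fid)))
  class(rep) <- "tx_sequence_report"
  rep
}

#' @export
print.tx_sequence_report <- function(x, ...) {
  cat(sprintf("<sequence report> %s (%s) — %d section(s)\n", x$feature,
              x$so_type, length(x$sections)))
  for (nm in names(x$sections)) {
    s <- x$sections[[nm]]
    n <- if (is.data.frame(s)) nrow(s)
      else if (nm == "residues") 1L
      else if (nm == "functional_annotation") nrow(s$direct)
      else length(s)
    cat(sprintf("  %-24s %s\n", nm, if (n == 0) "(empty)" else paste(n, "record(s)")))
  }
  invisible(x)
}

#' Marker report
#'
#' @param store A `tx_store`.
#' @param marker Marker id, or the marker feature's unique name.
#' @return A `tx_marker_report`: the marker's type/motif/alleles metadata,
#'   its location in 1-based display coordinates, and the per-genotype allele
#'   table.
#' @export
marker_report <- function(store, marker) {
  mk <- store$tables$marker
  mid <- if (is.numeric(marker)) as.integer(marker) else {
    fid <- resolve_feature(store, marker)
    mk$marker_id[match(fid, mk$feature_id)]
  }
  if (is.na(mid) || !mid %in% mk$marker_id) {
    stop("unknown marker: ", marker, call. = FALSE)
  }
  row <- mk[mk$marker_id == mid, , drop = FALSE]
  feats <- store$tables$feature
  loc <- store$tables$featureloc
  loc <- loc[loc$feature_id == row$feature_id, , drop = FALSE]
  location <- tibble::tibble(
    on = feats$unique_name[match(loc$srcfeature_id, feats$feature_id)],
    start = loc$fmin + 1L, end = loc$fmax)
  al <- store$tables$allele[store$tables$allele$marker_id == mid, , drop = FALSE]
  gt <- store$tables$genotype
  alleles <- tibble::tibble(
    genotype = gt$name[match(al$genotype_id, gt$genotype_id)],
    value = al$value) |> dplyr::arrange(.data$genotype)
  rep <- list(marker = feats$unique_name[match(row$feature_id, feats$feature_id)],
              marker_type = row$marker_type, motif = row$motif,
              ref_allele = row$ref_allele, alt_alleles = row$alt_alleles,
              location = location, alleles = alleles)
  class(rep) <- "tx_marker_report"
  rep
}

#' Experiment report
#'
#' @param store A `tx_store`.
#' @param experiment Experiment name or id.
#' @return A `tx_experiment_report`: design (libraries with replicate indices
#'   and sizes) and ontology condition terms.
#' @export
experiment_report <- function(store, experiment) {
  eid <- resolve_experiment(store, experiment)
  ex <- store$tables$experiment
  row <- ex[ex$experiment_id == eid, , drop = FALSE]
  gt <- store$tables$genotype
  terms <- store$tables$experiment_term
  terms <- terms[terms$experiment_id == eid, c("term_id", "value"), drop = FALSE]
  libs <- store$tables$seq_library
  libs <- libs[libs$experiment_id == eid,
               c("name", "replicate_index", "total_reads"), drop = FALSE]
  rep <- list(experiment = row$name,
              genotype = gt$name[match(row$genotype_id, gt$genotype_id)],
              condition_terms = tibble::as_tibble(terms),
              libraries = dplyr::arrange(tibble::as_tibble(libs),
                                         .data$replicate_index))
  class(rep) <- "tx_experiment_report"
  rep
}

#' Genotype report
#'
#' @param store A `tx_store`.
#' @param genotype Genotype name or id.
#' @return A `tx_genotype_report`: the ontology-described attributes plus all
#'   reported marker alleles.
#' @export
genotype_report <- function(store, genotype) {
  gid <- resolve_genotype(store, genotype)
  gt <- store$tables$genotype
  at <- store$tables$genotype_attr
  at <- at[at$genotype_id == gid, c("term_id", "value"), drop = FALSE]
  al <- store$tables$allele[store$tables$allele$genotype_id == gid, , drop = FALSE]
  mk <- store$tables$marker
  feats <- store$tables$feature
  mfid <- mk$feature_id[match(al$marker_id, mk$marker_id)]
  alleles <- tibble::tibble(
    marker = feats$unique_name[match(mfid, feats$feature_id)],
    marker_type = mk$marker_type[match(al$marker_id, mk$marker_id)],
    value = al$value) |> dplyr::arrange(.data$marker)
  rep <- list(genotype = gt$name[gt$genotype_id == gid],
              attributes = tibble::as_tibble(at), alleles = alleles)
  class(rep) <- "tx_genotype_report"
  rep
}

#' @export
print.tx_marker_report <- function(x, ...) {
  cat(sprintf("<marker report> %s (%s) at %s:%d-%d — %d allele(s)\n",
              x$marker, x$marker_type,
              if (nrow(x$location)) x$location$on[1] else "?",
              if (nrow(x$location)) x$location$start[1] else NA,
              if (nrow(x$location)) x$location$end[1] else NA,
              nrow(x$alleles)))
  invisible(x)
}

#' @export
print.tx_experiment_report <- function(x, ...) {
  cat(sprintf("<experiment report> %s — %d librar%s, %d condition term(s)\n",
              x$experiment, nrow(x$libraries),
              if (nrow(x$libraries) == 1) "y" else "ies",
              nrow(x$condition_terms)))
  invisible(x)
}

#' @export
print.tx_genotype_report <- function(x, ...) {
  cat(sprintf("<genotype report> %s — %d attribute(s), %d allele(s)\n",
              x$genotype, nrow(x$attributes), nrow(x$alleles)))
  invisible(x)
}

#' Serialize a report to JSON
#'
#' @param report Any report object (`tx_sequence_report`, `tx_marker_report`,
#'   `tx_experiment_report`, `tx_genotype_report`) or a `tx_query`.
#' @param pretty Pretty-print?
#' @return A JSON string.
#' @export
report_json <- function(report, pretty = TRUE) {
  strip <- function(x) {
    if (inherits(x, "ontology_graph")) {
      return(list(terms = x$terms[c("term_id", "name",
                                    if ("status" %in% names(x$terms)) "status")],
                  relations = x$relations))
    }
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, strip))
    x
  }
  jsonlite::toJSON(strip(unclass(report)), pretty = pretty, auto_unbox = TRUE,
                   na = "null", digits = NA)
}
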