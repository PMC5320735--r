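#' Query results
#'
#' Searches return a `tx_query`: one row per feature (deduplicated), sorted
#' by unique name unless another order is requested, with a `provenance`
#' attribute describing the filters applied. Results serialize to CSV with
#' [export_table()] and compose: [filter_by_marker()] and
#' [term_summary_for_result()] consume them directly.
#'
#' @name tx_query
NULL

new_tx_query <- function(rows, provenance) {
  rows <- tibble::as_tibble(rows)
  attr(rows, "provenance") <- provenance
  class(rows) <- unique(c("tx_query", class(rows)))
  rows
}

#' @export
print.tx_query <- function(x, ...) {
  cat("<query result> ", attr(x, "provenance"), "\n", sep = "")
  NextMethod()
}

#' One-row summary of a query result
#'
#' @param x A `tx_query`.
#' @param ... Ignored.
#' @return Tibble with the row count and provenance.
#' @export
glance.tx_query <- function(x, ...) {
  tibble::tibble(n_features = nrow(x), provenance = attr(x, "provenance"))
}

like_to_regex <- function(pattern) {
  esc <- gsub("([.\\\\+*?\\[\\]^$(){}=!<>|:#-])", "\\\\\\1", pattern, perl = TRUE)
  paste0("^", gsub("_", ".", gsub("%", ".*", esc, fixed = TRUE), fixed = TRUE), "$")
}

compile_pattern <- function(pattern, mode) {
  rx <- switch(mode,
               exact = paste0("^", gsub("([.\\\\+*?\\[\\]^$(){}=!<>|:#-])",
                                        "\\\\\\1", pattern, perl = TRUE), "$"),
               like = like_to_regex(pattern),
               regex = pattern)
  ok <- tryCatch({ suppressWarnings(grepl(rx, "")); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) {
    stop("invalid regular expression '", pattern, "': ",
         conditionMessage(ok), call. = FALSE)
  }
  rx
}

# aggregated term ids for one feature: its own annotations plus those of
# features related to it by part_of/derives_from, one hop (gene <- isoforms)
aggregated_terms <- function(store, fid) {
  ann <- store$tables$term_annotation
  rel <- store$tables$feature_relationship
  related <- rel$subject_id[rel$object_id == fid &
                              rel$predicate %in% c("part_of", "derives_from")]
  sort(unique(ann$term_id[ann$feature_id %in% c(fid, related)]))
}

query_rows <- function(store, fids, flags = NULL) {
  fids <- unname(fids)
  feats <- store$tables$feature
  rows <- feats[match(fids, feats$feature_id),
                c("feature_id", "unique_name", "display_name", "so_type",
                  "seqlen")]
  rows$terms <- vapply(fids, function(f)
    paste(aggregated_terms(store, f), collapse = "|"), character(1))
  if (!is.null(flags)) rows$flag <- unname(flags)
  rows[] <- lapply(rows, unname)
  dplyr::arrange(rows, .data$unique_name)
}

#' Search features by name
#'
#' `like` mode follows SQL wildcards (`%` any run, `_` one character,
#' case-insensitive by default); `exact` matches the whole name; `regex`
#' takes a regular expression. Matches against unique and display names. Rows
#' carry the aggregated term annotations of the feature and of its one-hop
#' `part_of`/`derives_from` members, so a gene row shows the annotation of
#' all its isoforms.
#'
#' @param store A `tx_store`.
#' @param pattern Non-empty search pattern.
#' @param mode `"like"` (default), `"exact"`, or `"regex"`.
#' @param so_type Optional SO CURIE to restrict the searched feature type.
#' @param ignore_case Case-insensitive matching (default `TRUE`).
#' @return A `tx_query`.
#' @export
search_by_name <- function(store, pattern, mode = c("like", "exact", "regex"),
                           so_type = NULL, ignore_case = TRUE) {
  mode <- match.arg(mode)
  stopifnot(nzchar(pattern))
  rx <- compile_pattern(pattern, mode)
  feats <- store$tables$feature
  if (!is.null(so_type)) feats <- feats[feats$so_type %in% so_type, , drop = FALSE]
  hit <- grepl(rx, feats$unique_name, ignore.case = ignore_case) |
    (!is.na(feats$display_name) &
       grepl(rx, feats$display_name, ignore.case = ignore_case))
  new_tx_query(query_rows(store, feats$feature_id[hit]),
               sprintf("name %s '%s'%s", mode, pattern,
                       if (is.null(so_type)) "" else
                         paste0(" [type ", paste(so_type, collapse = ","), "]")))
}

#' Search features by ontology term
#'
#' Returns features annotated at the term. With `include_inherited`, features
#' whose direct annotations lie below the term (so the term is inherited) are
#' included too; each row is flagged `direct` or `indirect`, with `direct`
#' taking precedence when both apply.
#'
#' @param store A `tx_store`.
#' @param graph An `ontology_graph` (e.g. from [get_ontology()]).
#' @param term_id Term CURIE.
#' @param include_inherited Include features annotated below the term
#'   (default `TRUE`).
#' @return A `tx_query` with a `flag` column.
#' @export
search_by_term <- function(store, graph, term_id, include_inherited = TRUE) {
  if (!has_term(graph, term_id)) {
    stop("term not found in ontology '", graph$ontology_name, "': ", term_id,
         call. = FALSE)
  }
  prop <- store_propagated(store, graph)
  at_term <- prop[prop$term_id == term_id, , drop = FALSE]
  if (!include_inherited) {
    at_term <- at_term[at_term$status == "direct", , drop = FALSE]
  }
  flags <- ifelse(at_term$status == "direct", "direct", "indirect")
  # direct wins if a feature somehow appears twice
  ord <- order(at_term$feature, flags)
  at_term <- at_term[ord, , drop = FALSE]
  keep <- !duplicated(at_term$feature)
  fids <- as.integer(at_term$feature[keep])
  rows <- query_rows(store, fids, flags = flags[ord][keep])
  new_tx_query(rows, sprintf("annotated %s %s",
                             if (include_inherited) "at or below" else "directly at",
                             term_id))
}

# propagated annotations of the whole store against one graph;
# features keyed by feature_id (as character, for propagate_annotations)
store_propagated <- function(store, graph) {
  ann <- store$tables$term_annotation
  ann <- ann[ann$term_id %in% graph$terms$term_id, , drop = FALSE]
  direct <- tibble::tibble(feature = as.character(ann$feature_id),
                           term_id = ann$term_id)
  suppressWarnings(propagate_annotations(graph, direct))
}

#' Search features by BLAST hit description
#'
#' Pattern modes as in [search_by_name()], matched against stored hit
#' descriptions; rows are the (deduplicated) query features that own a
#' matching hit.
#'
#' @inheritParams search_by_name
#' @return A `tx_query`.
#' @export
search_by_blast_description <- function(store, pattern,
                                        mode = c("like", "exact", "regex"),
                                        ignore_case = TRUE) {
  mode <- match.arg(mode)
  stopifnot(nzchar(pattern))
  rx <- compile_pattern(pattern, mode)
  hits <- store$tables$blast_hit
  fids <- unique(hits$feature_id[grepl(rx, hits$description,
                                       ignore.case = ignore_case)])
  new_tx_query(query_rows(store, fids),
               sprintf("blast description %s '%s'", mode, pattern))
}

#' Keep only features carrying markers
#'
#' Retains result rows whose feature has at least `min_count` markers of the
#' given type located on it, and attaches the count. Idempotent.
#'
#' @param result A `tx_query`.
#' @param store The `tx_store` the result came from.
#' @param marker_type `"SSR"` or `"SNP"`.
#' @param min_count Minimum number of markers (default 1).
#' @return A filtered `tx_query` with an `n_markers` column.
#' @export
filter_by_marker <- function(result, store, marker_type = c("SSR", "SNP"),
                             min_count = 1L) {
  marker_type <- match.arg(marker_type)
  counts <- marker_counts(store, marker_type)
  rows <- tibble::as_tibble(result)
  rows$n_markers <- dplyr::coalesce(
    counts$n[match(rows$feature_id, counts$srcfeature_id)], 0L)
  rows <- rows[rows$n_markers >= min_count, , drop = FALSE]
  new_tx_query(rows, paste0(attr(result, "provenance"), " + >=", min_count,
                            " ", marker_type, " marker(s)"))
}

# markers of a type per source feature they are located on
marker_counts <- function(store, marker_type) {
  mk <- store$tables$marker[store$tables$marker$marker_type == marker_type, ,
                            drop = FALSE]
  loc <- store$tables$featureloc
  loc <- loc[loc$feature_id %in% mk$feature_id, , drop = FALSE]
  dplyr::count(loc, .data$srcfeature_id, name = "n")
}

#' Term-count summary restricted to a query result
#'
#' The same multiple-annotation counting as [term_count_summary()], but over
#' the features present in the result table only — the "pie chart for the
#' result table" view.
#'
#' @param result A `tx_query`.
#' @param store The `tx_store` the result came from.
#' @param graph An `ontology_graph`.
#' @param focus Focus term CURIE.
#' @return A `tx_term_summary`.
#' @export
term_summary_for_result <- function(result, store, graph, focus) {
  ann <- store$tables$term_annotation
  ann <- ann[ann$feature_id %in% result$feature_id &
               ann$term_id %in% graph$terms$term_id, , drop = FALSE]
  direct <- tibble::tibble(feature = as.character(ann$feature_id),
                           term_id = ann$term_id)
  prop <- suppressWarnings(propagate_annotations(graph, direct))
  term_count_summary(graph, prop, focus)
}
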