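#' Ontology graphs
#'
#' A controlled vocabulary is held as a directed acyclic graph of terms.
#' Edges over the *closure predicates* (by default `is_a` and `part_of`, the
#' GO-standard propagation relations) define annotation inheritance: a feature
#' annotated to a term is implicitly annotated to every ancestor reachable
#' through those edges. Obsolete terms are loadable but carry no outgoing
#' closure edges and never take part in propagation or counting.
#'
#' @name ontology_graph
NULL

CLOSURE_PREDICATES_DEFAULT <- c("is_a", "part_of")

new_ontology_graph <- function(name, terms, relations,
                               closure_predicates = CLOSURE_PREDICATES_DEFAULT) {
  terms <- tibble::as_tibble(terms)
  relations <- tibble::as_tibble(relations)
  stopifnot(all(c("term_id", "name", "namespace", "definition", "is_obsolete") %in%
                  names(terms)))
  if (anyDuplicated(terms$term_id)) {
    dup <- unique(terms$term_id[duplicated(terms$term_id)])
    stop("duplicate term id(s): ", paste(sort(dup), collapse = ", "), call. = FALSE)
  }
  if (nrow(relations)) {
    dangling <- setdiff(unique(c(relations$subject_id, relations$object_id)),
                        terms$term_id)
    if (length(dangling)) {
      stop("relation endpoint(s) not declared as terms: ",
           paste(sort(dangling), collapse = ", "), call. = FALSE)
    }
    if (any(relations$subject_id == relations$object_id)) {
      stop("self-loop relation on: ",
           paste(unique(relations$subject_id[relations$subject_id ==
                                               relations$object_id]),
                 collapse = ", "), call. = FALSE)
    }
  }
  g <- structure(
    list(ontology_name = name, terms = terms, relations = relations,
         closure_predicates = closure_predicates,
         parents = NULL, cache = new.env(parent = emptyenv())),
    class = "ontology_graph"
  )
  g$parents <- closure_parent_map(g)
  cyc <- closure_cycle_nodes(g)
  if (length(cyc)) {
    stop("cycle among closure predicates involving: {",
         paste(sort(cyc), collapse = ", "), "}", call. = FALSE)
  }
  g
}

# parent adjacency over closure predicates; obsolete subjects contribute none
closure_parent_map <- function(graph) {
  obs <- graph$terms$term_id[graph$terms$is_obsolete]
  rel <- graph$relations
  if (nrow(rel)) {
    rel <- rel[rel$predicate %in% graph$closure_predicates &
                 !(rel$subject_id %in% obs), , drop = FALSE]
  }
  pm <- split(rel$object_id, factor(rel$subject_id, levels = graph$terms$term_id))
  lapply(pm, unique)
}

# nodes on (or between) directed cycles in the closure subgraph; empty if a DAG
closure_cycle_nodes <- function(graph) {
  nodes <- graph$terms$term_id
  parents <- graph$parents
  indeg <- vapply(parents, length, integer(1))     # edges out of node (to parents)
  # Kahn on subject -> parent edges; leftover nodes lie on/below a cycle.
  children <- new.env(parent = emptyenv())
  for (s in nodes) for (p in parents[[s]]) {
    assign(p, c(get0(p, envir = children, ifnotfound = character()), s),
           envir = children)
  }
  queue <- nodes[indeg == 0]
  removed <- 0L
  deg <- indeg
  names(deg) <- nodes
  while (length(queue)) {
    n <- queue[[1]]; queue <- queue[-1]; removed <- removed + 1L
    for (ch in get0(n, envir = children, ifnotfound = character())) {
      deg[[ch]] <- deg[[ch]] - 1L
      if (deg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (removed == length(nodes)) character() else names(deg)[deg > 0L]
}

#' Parse an OBO flat file into an ontology graph
#'
#' Reads OBO 1.2/1.4 `[Term]` stanzas (id, name, namespace, def, synonym,
#' xref, `is_a:` and `relationship: <label> <id>` lines, `is_obsolete:`).
#' Unknown relationship labels are kept verbatim as their own predicate.
#' Loading rejects duplicate term ids, relations to undeclared terms, and any
#' cycle over the closure predicates (the graph must be a DAG for annotation
#' inheritance to be well defined).
#'
#' @param x Path to an OBO file, or a character vector of OBO lines.
#' @param name Ontology name; defaults to the file's `ontology:` header or
#'   the CURIE prefix of the first term.
#' @param closure_predicates Relation labels along which annotations
#'   propagate (default `is_a`, `part_of`).
#' @return An `ontology_graph`: terms and relations as tibbles plus the
#'   closure configuration.
#' @examples
#' obo <- c("format-version: 1.2", "",
#'          "[Term]", "id: T:0", "name: root", "",
#'          "[Term]", "id: T:1", "name: child", "is_a: T:0 ! root")
#' g <- parse_obo(obo)
#' ancestors(g, "T:1")
#' @export
parse_obo <- function(x, name = NULL,
                      closure_predicates = CLOSURE_PREDICATES_DEFAULT) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1 && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }
  lines <- sub("\r$", "", lines)

  stanza_starts <- grep("^\\[", lines)
  header <- if (length(stanza_starts)) lines[seq_len(stanza_starts[1] - 1L)] else lines
  onto_header <- sub("^ontology: *", "", grep("^ontology:", header, value = TRUE))

  term_rows <- list()
  rel_rows <- list()
  if (length(stanza_starts)) {
    bounds <- c(stanza_starts, length(lines) + 1L)
    for (k in seq_along(stanza_starts)) {
      head_line <- lines[stanza_starts[k]]
      if (!identical(head_line, "[Term]")) next
      body <- lines[seq(stanza_starts[k] + 1L, bounds[k + 1L] - 1L)]
      body <- body[nzchar(body)]
      m <- regmatches(body, regexec("^([A-Za-z_-]+): ?(.*)$", body))
      keys <- vapply(m, function(x) if (length(x)) x[2] else NA_character_,
                     character(1))
      vals <- vapply(m, function(x) if (length(x)) x[3] else NA_character_,
                     character(1))
      val1 <- function(key) {
        v <- vals[keys == key]
        if (length(v)) v[[1]] else NA_character_
      }
      strip_comment <- function(v) trimws(sub(" *!.*$", "", v))
      id <- strip_comment(val1("id"))
      if (is.na(id)) stop("[Term] stanza without an id line", call. = FALSE)
      syns <- vals[keys == "synonym"]
      syns <- gsub('^"(.*)".*$', "\\1", syns)
      term_rows[[length(term_rows) + 1L]] <- tibble::tibble(
        term_id = id,
        name = val1("name"),
        namespace = val1("namespace"),
        definition = gsub('^"(.*)".*$', "\\1", val1("def")),
        is_obsolete = identical(strip_comment(val1("is_obsolete")), "true"),
        synonyms = list(syns),
        xrefs = list(strip_comment(vals[keys == "xref"]))
      )
      for (v in vals[keys == "is_a"]) {
        rel_rows[[length(rel_rows) + 1L]] <-
          tibble::tibble(subject_id = id, predicate = "is_a",
                         object_id = strip_comment(v))
      }
      for (v in vals[keys == "relationship"]) {
        parts <- strsplit(strip_comment(v), "[ \t]+")[[1]]
        if (length(parts) >= 2) {
          rel_rows[[length(rel_rows) + 1L]] <-
            tibble::tibble(subject_id = id, predicate = parts[1],
                           object_id = parts[2])
        }
      }
    }
  }
  terms <- if (length(term_rows)) dplyr::bind_rows(term_rows) else tibble::tibble(
    term_id = character(), name = character(), namespace = character(),
    definition = character(), is_obsolete = logical(),
    synonyms = list(), xrefs = list()
  )
  relations <- if (length(rel_rows)) dplyr::distinct(dplyr::bind_rows(rel_rows)) else
    tibble::tibble(subject_id = character(), predicate = character(),
                   object_id = character())
  if (is.null(name)) {
    name <- if (length(onto_header)) onto_header[[1]] else if (nrow(terms)) {
      sub(":.*$", "", terms$term_id[[1]])
    } else "ontology"
  }
  new_ontology_graph(name, terms, relations, closure_predicates)
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("<ontology_graph> %s: %d terms (%d obsolete), %d relations; closure over {%s}\n",
              x$ontology_name, nrow(x$terms), sum(x$terms$is_obsolete),
              nrow(x$relations), paste(x$closure_predicates, collapse = ", ")))
  invisible(x)
}

has_term <- function(graph, term_id) term_id %in% graph$terms$term_id

#' Ancestors of a term
#'
#' All terms reachable from `term_id` through the graph's closure predicates,
#' excluding the term itself. Ancestor sets are memoized on first use
#' (computed on demand rather than as a precomputed full closure table), so
#' repeated queries over large vocabularies stay cheap.
#'
#' @param graph An `ontology_graph`.
#' @param term_id A term CURIE present in the graph.
#' @return Sorted character vector of ancestor term ids.
#' @export
ancestors <- function(graph, term_id) {
  if (!has_term(graph, term_id)) {
    stop("term not found in ontology '", graph$ontology_name, "': ", term_id,
         call. = FALSE)
  }
  cache <- graph$cache
  stack <- term_id
  while (length(stack)) {
    t <- stack[[length(stack)]]
    if (!is.null(get0(t, envir = cache))) {
      stack <- stack[-length(stack)]
      next
    }
    ps <- graph$parents[[t]]
    missing <- ps[vapply(ps, function(p) is.null(get0(p, envir = cache)),
                         logical(1))]
    if (length(missing)) {
      stack <- c(stack, missing)
    } else {
      anc <- unique(c(ps, unlist(lapply(ps, get0, envir = cache),
                                 use.names = FALSE)))
      assign(t, sort(anc %||% character()), envir = cache)
      stack <- stack[-length(stack)]
    }
  }
  get(term_id, envir = cache)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_annotation_tbl <- function(direct) {
  if (is.data.frame(direct)) {
    stopifnot(all(c("feature", "term_id") %in% names(direct)))
    tibble::as_tibble(direct[c("feature", "term_id")])
  } else {
    tibble::tibble(
      feature = rep(names(direct), lengths(direct)),
      term_id = unlist(direct, use.names = FALSE) %||% character()
    )
  }
}

#' Propagate feature annotations through the ontology
#'
#' Extends each feature's directly asserted terms with every ancestor along
#' the closure predicates. The inherited set excludes the direct set, so the
#' two are always disjoint. Annotations to obsolete terms are kept as direct
#' assertions but excluded from inheritance, with a warning.
#'
#' @param graph An `ontology_graph`.
#' @param direct Direct annotations: either a tibble with columns `feature`
#'   and `term_id`, or a named list of term-id vectors keyed by feature.
#' @return A tibble with columns `feature`, `term_id`, `status`
#'   (`"direct"` or `"inherited"`).
#' @export
propagate_annotations <- function(graph, direct) {
  ann <- dplyr::distinct(as_annotation_tbl(direct))
  if (!nrow(ann)) {
    return(tibble::tibble(feature = character(), term_id = character(),
                          status = character()))
  }
  unknown <- setdiff(unique(ann$term_id), graph$terms$term_id)
  if (length(unknown)) {
    stop("annotation to unknown term(s): ", paste(sort(unknown), collapse = ", "),
         call. = FALSE)
  }
  obs <- intersect(unique(ann$term_id),
                   graph$terms$term_id[graph$terms$is_obsolete])
  if (length(obs)) {
    warning("annotation(s) to obsolete term(s) excluded from inheritance: ",
            paste(sort(obs), collapse = ", "), call. = FALSE)
  }
  anc_of <- function(tids) {
    tids <- setdiff(tids, obs)
    unique(unlist(lapply(tids, ancestors, graph = graph), use.names = FALSE)) %||%
      character()
  }
  out <- ann |>
    dplyr::group_by(.data$feature) |>
    dplyr::reframe({
      d <- unique(.data$term_id)
      inh <- setdiff(anc_of(d), d)
      tibble::tibble(term_id = c(d, inh),
                     status = rep(c("direct", "inherited"), c(length(d), length(inh))))
    }) |>
    dplyr::arrange(.data$feature, .data$status, .data$term_id)
  out
}

# term set (direct + inherited) per feature, from a propagated tibble
membership_sets <- function(propagated) {
  split(propagated$term_id, propagated$feature)
}

#' Per-child feature counts under a focus term
#'
#' For every direct child of `focus` (over the closure predicates), counts
#' the *distinct* features annotated at or below that child — i.e. whose
#' propagated term set contains the child. Because a feature may be annotated
#' under several children, child counts can legitimately sum to more than the
#' total of distinct features under the focus term (multiple-annotation
#' semantics, as in classification pie charts).
#'
#' @param graph An `ontology_graph`.
#' @param annotations A propagated annotation tibble from
#'   [propagate_annotations()].
#' @param focus CURIE of the focus term.
#' @return A `tx_term_summary` tibble (`term_id`, `name`, `n_features`), with
#'   attributes `focus` and `total` (distinct features at or below focus).
#' @export
term_count_summary <- function(graph, annotations, focus) {
  if (!has_term(graph, focus)) {
    stop("term not found in ontology '", graph$ontology_name, "': ", focus,
         call. = FALSE)
  }
  obs <- graph$terms$term_id[graph$terms$is_obsolete]
  rel <- graph$relations
  kids <- sort(unique(rel$subject_id[rel$object_id == focus &
                                       rel$predicate %in% graph$closure_predicates &
                                       !(rel$subject_id %in% obs)]))
  sets <- membership_sets(annotations)
  n_at_or_below <- function(t) sum(vapply(sets, function(s) t %in% s, logical(1)))
  out <- tibble::tibble(
    term_id = kids,
    name = graph$terms$name[match(kids, graph$terms$term_id)],
    n_features = vapply(kids, n_at_or_below, integer(1), USE.NAMES = FALSE)
  )
  attr(out, "focus") <- focus
  attr(out, "total") <- n_at_or_below(focus)
  class(out) <- c("tx_term_summary", class(out))
  out
}

#' @export
print.tx_term_summary <- function(x, ...) {
  cat(sprintf("Term summary under %s — %d distinct feature(s) at or below focus\n",
              attr(x, "focus"), attr(x, "total")))
  NextMethod()
}

#' Read a dbxref-to-ontology mapping table
#'
#' Two-column TAB or CSV file mapping external database identifiers (e.g.
#' InterPro accessions) to ontology term CURIEs, one pair per row
#' (interpro2go style). Lines starting with `!` or `#` are comments.
#' Malformed rows are skipped with a warning naming the line.
#'
#' @param path File path.
#' @return Tibble with columns `external_id`, `term_id`.
#' @export
read_dbxref_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^[!#]", lines) & nzchar(trimws(lines))
  rows <- lapply(which(keep), function(i) {
    parts <- strsplit(lines[[i]], "[\t,]")[[1]]
    parts <- trimws(parts)
    if (length(parts) < 2 || !nzchar(parts[1]) || !nzchar(parts[2])) {
      warning("malformed dbxref mapping row at line ", i, ": ", lines[[i]],
              call. = FALSE)
      return(NULL)
    }
    tibble::tibble(external_id = parts[1], term_id = parts[2])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows)) dplyr::distinct(dplyr::bind_rows(rows)) else
    tibble::tibble(external_id = character(), term_id = character())
}

#' Map external identifiers to ontology terms
#'
#' @param mapping A tibble from [read_dbxref_map()] (columns `external_id`,
#'   `term_id`).
#' @param external_ids Character vector of identifiers to map.
#' @return A list with `term_ids` (sorted unique CURIEs) and `unmapped`
#'   (identifiers with no mapping; reported, not fatal).
#' @export
map_dbxref <- function(mapping, external_ids) {
  ids <- unique(external_ids)
  hit <- mapping[mapping$external_id %in% ids, , drop = FALSE]
  list(term_ids = sort(unique(hit$term_id)),
       unmapped = sort(setdiff(ids, mapping$external_id)))
}

#' Reduced ontology subgraph for a set of annotated terms
#'
#' Induces the sub-DAG containing the given terms, all their ancestors over
#' the closure predicates, and every closure edge among retained terms —
#' the "reduced graph" shown in a sequence report's functional-annotation
#' section. Retained terms carry a `status` column: `"direct"` for input
#' terms, `"inherited"` for ancestors pulled in by closure.
#'
#' @param graph An `ontology_graph`.
#' @param terms Character vector of term CURIEs (all must exist in `graph`).
#' @return An `ontology_graph` whose `terms` tibble has an extra `status`
#'   column.
#' @export
annotation_subgraph <- function(graph, terms) {
  terms <- unique(terms)
  unknown <- setdiff(terms, graph$terms$term_id)
  if (length(unknown)) {
    stop("term(s) not found in ontology '", graph$ontology_name, "': ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)
  }
  anc <- unique(unlist(lapply(terms, ancestors, graph = graph),
                       use.names = FALSE)) %||% character()
  keep <- union(terms, anc)
  t <- graph$terms[graph$terms$term_id %in% keep, , drop = FALSE]
  t$status <- ifelse(t$term_id %in% terms, "direct", "inherited")
  t <- dplyr::arrange(t, .data$term_id)
  r <- graph$relations[graph$relations$subject_id %in% keep &
                         graph$relations$object_id %in% keep &
                         graph$relations$predicate %in% graph$closure_predicates, ,
                       drop = FALSE]
  sub <- new_ontology_graph(graph$ontology_name, t, r, graph$closure_predicates)
  sub
}

#' Bar-chart view of a term-count summary
#'
#' @param object A `tx_term_summary` from [term_count_summary()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.tx_term_summary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- ifelse(is.na(df$name), df$term_id, df$name)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, .data$n_features),
                                   y = .data$n_features)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "distinct features at or below term",
                  title = paste("Annotation counts under", attr(object, "focus")),
                  subtitle = sprintf("%d distinct feature(s) under focus; child slices may overlap",
                                     attr(object, "total"))) +
    ggplot2::theme_minimal()
}
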