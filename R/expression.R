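#' Replicate-structured expression experiments
#'
#' An experiment is one assayed condition, described by ontology terms (any
#' loaded vocabulary — e.g. anatomy terms for phenological state and sex) and
#' optionally tied to a genotype. Each experiment owns one sequencing library
#' per replicate; measured values (raw counts, RPKM, or any labelled measure)
#' attach to a (feature, library) pair. Raw counts may be non-integer, so
#' pseudo-aligned or otherwise fractional counts store unchanged.
#'
#' @name expression
NULL

#' Create an experiment
#'
#' @param store A `tx_store`.
#' @param name Unique experiment name (e.g. `"male_larvae"`).
#' @param condition_terms Ontology descriptors: a character vector of CURIEs,
#'   or a tibble with `term_id` and optional `value`. Each must resolve in a
#'   loaded ontology when any is loaded.
#' @param genotype Optional genotype name or id.
#' @return The experiment id.
#' @export
create_experiment <- function(store, name, condition_terms = NULL,
                              genotype = NULL) {
  tbl <- store$tables$experiment
  if (name %in% tbl$name) {
    stop("an experiment named '", name, "' already exists", call. = FALSE)
  }
  terms <- if (is.null(condition_terms)) {
    tibble::tibble(term_id = character(), value = character())
  } else if (is.data.frame(condition_terms)) {
    tibble::tibble(term_id = condition_terms$term_id,
                   value = if ("value" %in% names(condition_terms))
                     as.character(condition_terms$value) else NA_character_)
  } else {
    tibble::tibble(term_id = as.character(condition_terms), value = NA_character_)
  }
  for (t in terms$term_id) {
    if (length(store$ontologies) && is.na(find_store_term(store, t))) {
      stop("condition term not found in the loaded ontologies: ", t,
           call. = FALSE)
    }
  }
  gid <- if (is.null(genotype)) NA_integer_ else resolve_genotype(store, genotype)
  id <- next_id(store, "experiment")
  store$tables$experiment <- dplyr::bind_rows(tbl, tibble::tibble(
    experiment_id = id, name = name, genotype_id = gid))
  if (nrow(terms)) {
    store$tables$experiment_term <- dplyr::bind_rows(
      store$tables$experiment_term,
      tibble::tibble(
        experiment_term_id = next_id(store, "experiment_term") +
          seq_len(nrow(terms)) - 1L,
        experiment_id = id, term_id = terms$term_id, value = terms$value))
  }
  audit(store, "create_experiment", name)
  invisible(id)
}

resolve_experiment <- function(store, experiment) {
  tbl <- store$tables$experiment
  id <- if (is.numeric(experiment)) {
    if (experiment %in% tbl$experiment_id) as.integer(experiment) else NA_integer_
  } else tbl$experiment_id[match(experiment, tbl$name)]
  if (is.na(id)) stop("unknown experiment: ", experiment, call. = FALSE)
  id
}

#' Add a sequencing library (one replicate) to an experiment
#'
#' @param store A `tx_store`.
#' @param experiment Experiment name or id.
#' @param name Unique library name.
#' @param replicate_index Positive replicate number, unique within the
#'   experiment.
#' @param total_reads Optional library size (mapped reads), required later
#'   for RPKM.
#' @return The library id.
#' @export
add_library <- function(store, experiment, name, replicate_index,
                        total_reads = NULL) {
  eid <- resolve_experiment(store, experiment)
  tbl <- store$tables$seq_library
  if (name %in% tbl$name) {
    stop("a library named '", name, "' already exists", call. = FALSE)
  }
  replicate_index <- as.integer(replicate_index)
  stopifnot(replicate_index >= 1L)
  if (any(tbl$experiment_id == eid & tbl$replicate_index == replicate_index)) {
    stop("replicate index ", replicate_index,
         " is already used in this experiment", call. = FALSE)
  }
  id <- next_id(store, "seq_library")
  store$tables$seq_library <- dplyr::bind_rows(tbl, tibble::tibble(
    library_id = id, name = name, experiment_id = eid,
    replicate_index = replicate_index,
    total_reads = if (is.null(total_reads)) NA_integer_ else
      as.integer(total_reads)))
  audit(store, "add_library", name)
  invisible(id)
}

resolve_library <- function(store, library) {
  tbl <- store$tables$seq_library
  id <- if (is.numeric(library)) {
    if (library %in% tbl$library_id) as.integer(library) else NA_integer_
  } else tbl$library_id[match(library, tbl$name)]
  if (is.na(id)) stop("unknown library: ", library, call. = FALSE)
  id
}

#' Store a measured expression value
#'
#' `(feature, library, measure)` is unique; re-storing overwrites.
#'
#' @param store A `tx_store`.
#' @param feature,library Names or ids.
#' @param measure Measure label (`"raw_count"`, `"RPKM"`, or any other).
#' @param value Non-negative numeric.
#' @return The expression value id.
#' @export
add_expression_value <- function(store, feature, library, measure, value) {
  fid <- resolve_feature(store, feature)
  lid <- resolve_library(store, library)
  value <- as.double(value)
  if (is.na(value) || value < 0) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  tbl <- store$tables$expression_value
  hit <- which(tbl$feature_id == fid & tbl$library_id == lid &
                 tbl$measure == measure)
  if (length(hit)) {
    store$tables$expression_value$value[hit[1]] <- value
    return(invisible(tbl$expression_value_id[hit[1]]))
  }
  id <- next_id(store, "expression_value")
  store$tables$expression_value <- dplyr::bind_rows(tbl, tibble::tibble(
    expression_value_id = id, feature_id = fid, library_id = lid,
    measure = measure, value = value))
  invisible(id)
}

#' Reads per kilobase per million mapped reads
#'
#' `raw_count * 1e9 / (transcript_length_bp * library_total_reads)`: the read
#' count normalized by transcript length and by library size, on the standard
#' per-kilobase x per-million scale.
#'
#' @param raw_count Non-negative read count (may be fractional).
#' @param transcript_length_bp Transcript length in bp (> 0).
#' @param library_total_reads Total mapped reads in the library (> 0).
#' @return RPKM value(s); vectorized over its arguments.
#' @examples
#' compute_rpkm(10, 500, 1e6)  # 20
#' @export
compute_rpkm <- function(raw_count, transcript_length_bp, library_total_reads) {
  if (any(is.na(raw_count)) || any(raw_count < 0)) {
    stop("raw_count must be non-negative", call. = FALSE)
  }
  if (any(is.na(transcript_length_bp)) || any(transcript_length_bp <= 0)) {
    stop("transcript_length_bp must be positive", call. = FALSE)
  }
  if (any(is.na(library_total_reads)) || any(library_total_reads <= 0)) {
    stop("library_total_reads must be positive", call. = FALSE)
  }
  # as doubles: the bp x reads product overflows integer arithmetic
  raw_count * 1e9 / (as.double(transcript_length_bp) *
                       as.double(library_total_reads))
}

#' Compute and store RPKM for every counted feature of a library
#'
#' Converts each stored `raw_count` of the library into an `RPKM` value using
#' the feature's sequence length and the library's total reads. Features
#' without a sequence length (e.g. residue-less gene loci) are skipped with a
#' warning. Rerunning overwrites idempotently.
#'
#' @param store A `tx_store`.
#' @param library Library name or id (must have `total_reads`).
#' @return Number of RPKM values written, invisibly; warnings are attached as
#'   the `"skipped"` attribute (skipped feature names).
#' @export
rpkm_for_library <- function(store, library) {
  lid <- resolve_library(store, library)
  lib <- store$tables$seq_library
  total <- lib$total_reads[lib$library_id == lid]
  if (is.na(total)) {
    stop("library has no total_reads; RPKM undefined", call. = FALSE)
  }
  ev <- store$tables$expression_value
  counts <- ev[ev$library_id == lid & ev$measure == "raw_count", , drop = FALSE]
  feats <- store$tables$feature
  len <- feats$seqlen[match(counts$feature_id, feats$feature_id)]
  no_len <- is.na(len)
  if (any(no_len)) {
    warning("feature(s) without sequence length skipped for RPKM: ",
            paste(feats$unique_name[match(counts$feature_id[no_len],
                                          feats$feature_id)], collapse = ", "),
            call. = FALSE)
  }
  written <- 0L
  for (i in which(!no_len)) {
    add_expression_value(store, counts$feature_id[i], lid, "RPKM",
                         compute_rpkm(counts$value[i], len[i], total))
    written <- written + 1L
  }
  audit(store, "rpkm_for_library", lib$name[lib$library_id == lid])
  out <- written
  attr(out, "skipped") <- feats$unique_name[match(counts$feature_id[no_len],
                                                  feats$feature_id)]
  invisible(out)
}

#' Expression profile of a feature across experiments
#'
#' One row per (experiment, measure) with at least one stored replicate
#' value: arithmetic mean, sample standard deviation (n-1 denominator,
#' reported as 0 when n = 1 with `n` exposed so callers can tell the two
#' apart), and the experiment's genotype for grouped display.
#'
#' @param store A `tx_store`.
#' @param feature Feature name or id.
#' @param experiments Optional experiment names/ids to restrict to.
#' @param measure Optional measure label (e.g. `"RPKM"`); default all.
#' @return A `tx_expression_profile` tibble: `experiment`, `genotype`,
#'   `measure`, `mean`, `sd`, `n`.
#' @export
expression_profile <- function(store, feature, experiments = NULL,
                               measure = NULL) {
  fid <- resolve_feature(store, feature)
  ev <- store$tables$expression_value
  ev <- ev[ev$feature_id == fid, , drop = FALSE]
  if (!is.null(measure)) ev <- ev[ev$measure %in% measure, , drop = FALSE]
  lib <- store$tables$seq_library
  ex <- store$tables$experiment
  gt <- store$tables$genotype
  df <- dplyr::left_join(ev, lib[c("library_id", "experiment_id")],
                         by = "library_id")
  if (!is.null(experiments)) {
    eids <- vapply(experiments, resolve_experiment, integer(1), store = store)
    df <- df[df$experiment_id %in% eids, , drop = FALSE]
  }
  out <- df |>
    dplyr::group_by(.data$experiment_id, .data$measure) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(
      experiment = ex$name[match(.data$experiment_id, ex$experiment_id)],
      genotype = gt$name[match(ex$genotype_id[match(.data$experiment_id,
                                                    ex$experiment_id)],
                               gt$genotype_id)]) |>
    dplyr::select("experiment", "genotype", "measure", "mean", "sd", "n") |>
    dplyr::arrange(.data$experiment, .data$measure)
  attr(out, "feature") <- feats_name(store, fid)
  class(out) <- c("tx_expression_profile", class(out))
  out
}

feats_name <- function(store, fid) {
  store$tables$feature$unique_name[store$tables$feature$feature_id == fid]
}

#' Mean/SD bar chart of an expression profile
#'
#' @param object A `tx_expression_profile`.
#' @param ... Ignored.
#' @return A ggplot object: one bar per condition with an SD error bar,
#'   faceted by measure (and genotype when present).
#' @export
autoplot.tx_expression_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$experiment, y = .data$mean)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::labs(x = "condition", y = "mean of replicates",
                  title = paste("Expression profile:", attr(object, "feature"))) +
    ggplot2::theme_minimal()
  if (any(!is.na(df$genotype))) {
    p + ggplot2::facet_grid(genotype ~ measure, scales = "free_y")
  } else {
    p + ggplot2::facet_wrap(~measure, scales = "free_y")
  }
}
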