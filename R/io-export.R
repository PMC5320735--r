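#' Export sequences to FASTA
#'
#' Residues round-trip exactly: re-loading the export yields the identical
#' sequence set. Residue-less features in the selection are skipped with a
#' warning.
#'
#' @param store A `tx_store`.
#' @param features Character vector of unique names (default: every feature
#'   with residues).
#' @param path Optional file to write.
#' @param width Line-wrap width for residues.
#' @return Character vector of FASTA lines (invisibly when written).
#' @export
export_fasta <- function(store, features = NULL, path = NULL, width = 70L) {
  tbl <- store$tables$feature
  if (is.null(features)) {
    tbl <- tbl[!is.na(tbl$residues), , drop = FALSE]
  } else {
    miss <- setdiff(features, tbl$unique_name)
    if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "),
                           call. = FALSE)
    tbl <- tbl[match(features, tbl$unique_name), , drop = FALSE]
    empty <- is.na(tbl$residues)
    if (any(empty)) {
      warning("feature(s) without residues skipped: ",
              paste(tbl$unique_name[empty], collapse = ", "), call. = FALSE)
      tbl <- tbl[!empty, , drop = FALSE]
    }
  }
  tbl <- tbl[order(tbl$unique_name), , drop = FALSE]
  lines <- unlist(lapply(seq_len(nrow(tbl)), function(i) {
    res <- tbl$residues[i]
    starts <- seq(1, nchar(res), by = width)
    c(paste0(">", tbl$unique_name[i],
             ifelse(is.na(tbl$display_name[i]), "",
                    paste0(" ", tbl$display_name[i]))),
      substring(res, starts, pmin(starts + width - 1L, nchar(res))))
  }), use.names = FALSE) %||% character()
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Export the complete functional annotation in ANNOT form
#'
#' TAB-separated feature/term pairs over all annotation sources, sorted and
#' de-duplicated, re-loadable by [load_annot()] to give back the identical
#' annotation set.
#'
#' @param store A `tx_store`.
#' @param path Optional file to write.
#' @return Character vector of ANNOT lines.
#' @export
export_annot <- function(store, path = NULL) {
  ann <- store$tables$term_annotation
  feats <- store$tables$feature
  rows <- dplyr::distinct(tibble::tibble(
    feature = feats$unique_name[match(ann$feature_id, feats$feature_id)],
    term_id = ann$term_id))
  rows <- dplyr::arrange(rows, .data$feature, .data$term_id)
  lines <- if (nrow(rows)) paste(rows$feature, rows$term_id, sep = "\t") else
    character()
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Serialize a query result (or any tibble) to CSV
#'
#' Fields containing delimiters or quotes are quoted, so result tables import
#' cleanly into spreadsheets.
#'
#' @param result A `tx_query` or any data frame.
#' @param path Optional file to write.
#' @return A single CSV string (invisibly when written).
#' @export
export_table <- function(result, path = NULL) {
  df <- tibble::as_tibble(result)
  df <- df[!vapply(df, is.list, logical(1))]
  csv <- readr::format_csv(df)
  if (!is.null(path)) {
    writeLines(sub("\n$", "", csv), path)
    return(invisible(csv))
  }
  csv
}
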