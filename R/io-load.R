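#' Load reports
#'
#' Every bulk loader returns a `tx_load_report`: how many records were read,
#' how many were loaded, how many skipped, and a warning table (record/line
#' number, message). Warnings are never fatal; `read = loaded + skipped`
#' always holds.
#'
#' @name tx_load_report
NULL

new_load_report <- function(read, loaded, skipped, warnings = NULL) {
  warnings <- warnings %||% tibble::tibble(line = integer(), message = character())
  stopifnot(read == loaded + skipped)
  structure(list(records_read = as.integer(read), records_loaded = as.integer(loaded),
                 records_skipped = as.integer(skipped),
                 warnings = tibble::as_tibble(warnings)),
            class = "tx_load_report")
}

#' @export
print.tx_load_report <- function(x, ...) {
  cat(sprintf("<load report> read %d, loaded %d, skipped %d, %d warning(s)\n",
              x$records_read, x$records_loaded, x$records_skipped,
              nrow(x$warnings)))
  if (nrow(x$warnings)) {
    for (i in seq_len(min(nrow(x$warnings), 10))) {
      cat(sprintf("  [line %s] %s\n", x$warnings$line[i], x$warnings$message[i]))
    }
    if (nrow(x$warnings) > 10) cat("  ...\n")
  }
  invisible(x)
}

warn_collector <- function() {
  rows <- list()
  list(add = function(line, message) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(line = as.integer(line),
                                                 message = message)
  },
  tbl = function() {
    if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(line = integer(), message = character())
  })
}

# common GFF3 / toy-SO type vocabulary
TX_SO_TYPES <- c(
  gene = "SO:0000704", mRNA = "SO:0000234", transcript = "SO:0000673",
  exon = "SO:0000147", CDS = "SO:0000316",
  five_prime_UTR = "SO:0000204", three_prime_UTR = "SO:0000205",
  contig = "SO:0000149", region = "SO:0000001",
  SNP = "SO:0000694", microsatellite = "SO:0000289",
  polypeptide_domain = "SO:0000417", sequence_feature = "SO:0000110"
)

#' Load transcript sequences from a FASTA file
#'
#' One feature per record; the unique name is the first whitespace-delimited
#' token of the header, residues are stored verbatim (case preserved) and
#' `seqlen` is set from them. Duplicate names within the file and empty
#' sequences are skipped with a warning.
#'
#' @param store A `tx_store`.
#' @param path FASTA file.
#' @param so_type Sequence Ontology CURIE for the records (e.g. the contig
#'   term for Newbler isotigs).
#' @param organism Organism id or `"Genus species"`.
#' @return A `tx_load_report`.
#' @export
load_fasta <- function(store, path, so_type, organism) {
  seqs <- Biostrings::readBStringSet(path)
  wc <- warn_collector()
  loaded <- 0L; skipped <- 0L
  seen <- character()
  for (i in seq_along(seqs)) {
    header <- names(seqs)[i]
    nm <- strsplit(header, "[ \t]+")[[1]][1]
    res <- as.character(seqs[[i]])
    if (nm %in% seen) {
      skipped <- skipped + 1L
      wc$add(i, paste0("duplicate record name '", nm, "' skipped"))
      next
    }
    if (!nzchar(res)) {
      skipped <- skipped + 1L
      wc$add(i, paste0("empty sequence for '", nm, "' skipped"))
      next
    }
    seen <- c(seen, nm)
    display <- if (nchar(header) > nchar(nm)) trimws(substring(header, nchar(nm) + 1)) else
      NA_character_
    upsert_feature(store, nm, so_type, organism, residues = res,
                   display_name = if (is.na(display) || !nzchar(display))
                     NA_character_ else display)
    loaded <- loaded + 1L
  }
  audit(store, "load_fasta", path)
  new_load_report(length(seqs), loaded, skipped, wc$tbl())
}

#' Load residue-less features from a plain name list
#'
#' One name per line (e.g. Newbler isogroups, gene loci without sequence).
#' Blank lines are ignored; duplicates are skipped with a warning.
#'
#' @inheritParams load_fasta
#' @param path Text file, one feature name per line.
#' @return A `tx_load_report`.
#' @export
load_feature_list <- function(store, path, so_type, organism) {
  lines <- readLines(path, warn = FALSE)
  wc <- warn_collector()
  loaded <- 0L; skipped <- 0L; read <- 0L
  seen <- character()
  for (i in seq_along(lines)) {
    nm <- trimws(lines[[i]])
    if (!nzchar(nm)) next
    read <- read + 1L
    if (nm %in% seen) {
      skipped <- skipped + 1L
      wc$add(i, paste0("duplicate name '", nm, "' skipped"))
      next
    }
    seen <- c(seen, nm)
    upsert_feature(store, nm, so_type, organism)
    loaded <- loaded + 1L
  }
  audit(store, "load_feature_list", path)
  new_load_report(read, loaded, skipped, wc$tbl())
}

#' Load structural annotation from GFF3
#'
#' One feature per GFF record (column 3 mapped to a Sequence Ontology term,
#' unknown types falling back to `region` with a warning), one location per
#' record converted from 1-based inclusive to interbase, and one `part_of`
#' relationship per `Parent=` attribute. Loading is two-pass, so a `Parent`
#' defined later in the file resolves. Column-1 seqids must name features
#' already in the store (the transcripts); records on unknown seqids are
#' skipped with a warning, and records with `end < start` are rejected.
#'
#' @param store A `tx_store`.
#' @param path GFF3 file.
#' @return A `tx_load_report`.
#' @export
load_gff3 <- function(store, path) {
  lines <- readLines(path, warn = FALSE)
  wc <- warn_collector()
  fasta_at <- grep("^##FASTA", lines)
  if (length(fasta_at)) lines <- lines[seq_len(fasta_at[1] - 1L)]
  is_data <- !grepl("^#", lines) & nzchar(trimws(lines))
  read <- sum(is_data)
  rejected <- 0L
  keep <- rep(TRUE, length(lines))
  for (i in which(is_data)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    bad <- length(parts) < 8 ||
      is.na(suppressWarnings(as.integer(parts[4]))) ||
      is.na(suppressWarnings(as.integer(parts[5]))) ||
      as.integer(parts[5]) < as.integer(parts[4])
    if (bad) {
      keep[i] <- FALSE
      rejected <- rejected + 1L
      wc$add(i, "malformed GFF3 record rejected (bad columns or end < start)")
    }
  }
  tmp <- tempfile(fileext = ".gff3")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines[keep], tmp)

  gr <- rtracklayer::import(tmp, format = "gff3")
  df <- as.data.frame(gr)
  n <- nrow(df)
  loaded <- 0L; skipped <- rejected

  org_of <- function(fid) store$tables$feature$organism_id[
    store$tables$feature$feature_id == fid]

  # pass 1: create features
  ids <- character(n)
  src_ids <- integer(n)
  for (i in seq_len(n)) {
    src <- resolve_feature(store, as.character(df$seqnames[i]), required = FALSE)
    src_ids[i] <- src
    if (is.na(src)) {
      skipped <- skipped + 1L
      wc$add(i, paste0("seqid '", df$seqnames[i], "' not in store; record skipped"))
      next
    }
    type <- as.character(df$type[i])
    so <- if (type %in% names(TX_SO_TYPES)) TX_SO_TYPES[[type]]
      else if (grepl("^SO:\\d+$", type)) type
      else {
        wc$add(i, paste0("unknown feature type '", type, "'; stored as region"))
        TX_SO_TYPES[["region"]]
      }
    nm <- if (!is.null(df$ID) && !is.na(df$ID[i])) df$ID[i] else
      sprintf("gff_%s_%d", df$seqnames[i], i)
    ids[i] <- nm
    upsert_feature(store, nm, so, org_of(src))
    loaded <- loaded + 1L
  }
  # pass 2: locations and Parent relationships
  for (i in seq_len(n)) {
    if (is.na(src_ids[i])) next
    strand <- switch(as.character(df$strand[i]), "+" = 1L, "-" = -1L, 0L)
    phase <- if (!is.null(df$phase)) suppressWarnings(as.integer(df$phase[i])) else
      NA_integer_
    add_location(store, ids[i], src_ids[i],
                 fmin = df$start[i] - 1L, fmax = df$end[i],
                 strand = strand, phase = phase)
    parents <- if (!is.null(df$Parent)) unlist(df$Parent[i]) else character()
    for (p in parents) {
      pid <- resolve_feature(store, p, required = FALSE)
      if (is.na(pid)) {
        wc$add(i, paste0("Parent '", p, "' not found; relationship skipped"))
      } else if (pid != resolve_feature(store, ids[i])) {
        add_relationship(store, ids[i], "part_of", p)
      }
    }
  }
  audit(store, "load_gff3", path)
  new_load_report(read, loaded, read - loaded, wc$tbl())
}

#' Load BLAST results from NCBI BLAST XML
#'
#' One hit record per HSP. Query definitions resolve to stored features by
#' their first whitespace-delimited token; HSPs of unknown queries are skipped
#' with a warning. Percent identity is `identities / alignment length * 100`;
#' query coordinates are converted to interbase. Malformed XML aborts the
#' load.
#'
#' @param store A `tx_store`.
#' @param path BLAST XML (`BlastOutput`) file.
#' @param analysis Optional [add_analysis()] id; defaults to a run recorded
#'   from the file's program/version header.
#' @return A `tx_load_report`.
#' @export
load_blast_xml <- function(store, path, analysis = NULL) {
  doc <- xml2::read_xml(path)
  db_name <- xml2::xml_text(xml2::xml_find_first(doc, ".//BlastOutput_db"))
  if (is.null(analysis)) {
    analysis <- add_analysis(
      store,
      program = xml2::xml_text(xml2::xml_find_first(doc, ".//BlastOutput_program")),
      version = xml2::xml_text(xml2::xml_find_first(doc, ".//BlastOutput_version")),
      parameters = "", timestamp = "")
  }
  wc <- warn_collector()
  read <- 0L; loaded <- 0L
  iters <- xml2::xml_find_all(doc, ".//Iteration")
  for (it in iters) {
    qdef <- xml2::xml_text(xml2::xml_find_first(it, ".//Iteration_query-def"))
    qname <- strsplit(qdef, "[ \t]+")[[1]][1]
    qid <- resolve_feature(store, qname, required = FALSE)
    hits <- xml2::xml_find_all(it, ".//Hit")
    for (hit in hits) {
      acc <- xml2::xml_text(xml2::xml_find_first(hit, ".//Hit_accession"))
      def <- xml2::xml_text(xml2::xml_find_first(hit, ".//Hit_def"))
      hsps <- xml2::xml_find_all(hit, ".//Hsp")
      for (hsp in hsps) {
        read <- read + 1L
        if (is.na(qid)) next
        num <- function(tag) as.numeric(xml2::xml_text(
          xml2::xml_find_first(hsp, paste0(".//", tag))))
        add_blast_hit(store, qid, acc, def,
                      e_value = num("Hsp_evalue"),
                      bit_score = num("Hsp_bit-score"),
                      identity_pct = num("Hsp_identity") / num("Hsp_align-len") * 100,
                      query_start = num("Hsp_query-from") - 1L,
                      query_end = num("Hsp_query-to"),
                      db_name = db_name, analysis_id = analysis)
        loaded <- loaded + 1L
      }
    }
    if (is.na(qid)) {
      wc$add(NA_integer_,
             paste0("query '", qname, "' not in store; its HSPs were skipped"))
    }
  }
  audit(store, "load_blast_xml", path)
  new_load_report(read, loaded, read - loaded, wc$tbl())
}

#' Load Blast2GO ANNOT functional annotation
#'
#' TAB-separated rows: feature name, term CURIE (`GO:` or `EC:` style),
#' optional description. Rows naming unknown features, or terms that fail to
#' resolve in the loaded ontologies, are skipped with the line number.
#' Reloading is idempotent.
#'
#' @param store A `tx_store`.
#' @param path ANNOT file.
#' @param source Annotation source recorded per row (default `"blast2go"`).
#' @return A `tx_load_report`.
#' @export
load_annot <- function(store, path, source = "blast2go") {
  lines <- readLines(path, warn = FALSE)
  wc <- warn_collector()
  read <- 0L; loaded <- 0L
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[[i]])) || grepl("^[!#]", lines[[i]])) next
    read <- read + 1L
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) {
      wc$add(i, "malformed ANNOT row (need feature<TAB>term)")
      next
    }
    fid <- resolve_feature(store, trimws(parts[1]), required = FALSE)
    term <- trimws(parts[2])
    if (is.na(fid)) {
      wc$add(i, paste0("unknown feature '", parts[1], "'; row skipped"))
      next
    }
    if (!term_resolves(store, term)) {
      wc$add(i, paste0("term '", term, "' not found in loaded ontologies; row skipped"))
      next
    }
    add_term_annotation(store, fid, term, source = source)
    loaded <- loaded + 1L
  }
  audit(store, "load_annot", path)
  new_load_report(read, loaded, read - loaded, wc$tbl())
}

#' Load InterProScan tabular results
#'
#' One protein-domain feature plus its location (1-based match coordinates
#' converted to interbase) per row; InterPro accessions are mapped through a
#' dbxref-to-ontology table to term annotations (source `dbxref-mapped`), and
#' a GO column, when present, is loaded directly (source `interproscan`).
#' Unmapped InterPro accessions are reported, not fatal.
#'
#' @param store A `tx_store`.
#' @param path InterProScan TSV file.
#' @param dbxref_mapping Mapping tibble from [read_dbxref_map()] (may be
#'   empty).
#' @param columns 1-based column positions, InterProScan 5 layout by default:
#'   `feature`, `signature`, `start`, `end`, `interpro`, `go`.
#' @return A `tx_load_report`.
#' @export
load_interproscan <- function(store, path, dbxref_mapping = NULL,
                              columns = list(feature = 1, signature = 5,
                                             start = 7, end = 8,
                                             interpro = 12, go = 14)) {
  dbxref_mapping <- dbxref_mapping %||%
    tibble::tibble(external_id = character(), term_id = character())
  lines <- readLines(path, warn = FALSE)
  wc <- warn_collector()
  read <- 0L; loaded <- 0L
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[[i]])) || grepl("^#", lines[[i]])) next
    read <- read + 1L
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    cell <- function(j) if (!is.null(j) && j <= length(parts)) trimws(parts[[j]]) else ""
    fid <- resolve_feature(store, cell(columns$feature), required = FALSE)
    if (is.na(fid)) {
      wc$add(i, paste0("unknown feature '", cell(columns$feature), "'; row skipped"))
      next
    }
    start1 <- suppressWarnings(as.integer(cell(columns$start)))
    end1 <- suppressWarnings(as.integer(cell(columns$end)))
    if (is.na(start1) || is.na(end1) || end1 < start1) {
      wc$add(i, "bad match coordinates; row skipped")
      next
    }
    sig <- cell(columns$signature)
    dom_name <- paste(cell(columns$feature), sig, start1, end1, sep = "_")
    org <- store$tables$feature$organism_id[store$tables$feature$feature_id == fid]
    upsert_feature(store, dom_name, TX_SO_TYPES[["polypeptide_domain"]], org,
                   display_name = sig)
    add_location(store, dom_name, fid, fmin = start1 - 1L, fmax = end1)
    ipr <- cell(columns$interpro)
    if (nzchar(ipr) && ipr != "-") {
      mapped <- map_dbxref(dbxref_mapping, ipr)
      for (t in mapped$term_ids) {
        add_term_annotation(store, fid, t, source = "dbxref-mapped")
      }
      if (length(mapped$unmapped)) {
        wc$add(i, paste0("no ontology mapping for '", ipr, "'"))
      }
    }
    go <- cell(columns$go)
    if (nzchar(go) && go != "-") {
      for (t in strsplit(go, "|", fixed = TRUE)[[1]]) {
        if (term_resolves(store, t)) {
          add_term_annotation(store, fid, t, source = "interproscan")
        } else {
          wc$add(i, paste0("GO term '", t, "' not found; annotation skipped"))
        }
      }
    }
    loaded <- loaded + 1L
  }
  audit(store, "load_interproscan", path)
  new_load_report(read, loaded, read - loaded, wc$tbl())
}

#' Load SNP/SSR markers from VCF
#'
#' One marker per VCF record, located at `(POS-1, POS-1+len(REF))` interbase
#' on the CHROM transcript. SNPs store REF/ALT; SSRs take their motif from
#' the INFO key `MOTIF` when present. Per-sample GT fields become allele
#' records translated to allele strings (e.g. `1/1` with REF A, ALT G becomes
#' `"G/G"`); missing genotypes (`./.`) store nothing. Records on transcripts
#' not in the store are skipped with a warning, as are samples without a
#' genotype mapping.
#'
#' @param store A `tx_store`.
#' @param path VCF 4.x file (plain text).
#' @param marker_type `"SNP"` or `"SSR"`.
#' @param genotype_column_map Named character vector mapping VCF sample
#'   columns to stored genotype names; defaults to the identity mapping.
#' @return A `tx_load_report`.
#' @export
load_vcf_markers <- function(store, path, marker_type = c("SNP", "SSR"),
                             genotype_column_map = NULL) {
  marker_type <- match.arg(marker_type)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  n <- nrow(fix)
  wc <- warn_collector()
  loaded <- 0L
  samples <- if (ncol(vcf@gt) > 1) colnames(vcf@gt)[-1] else character()
  gmap <- genotype_column_map %||% stats::setNames(samples, samples)
  gt <- if (length(samples) && n > 0) {
    vcfR::extract.gt(vcf, element = "GT")
  } else NULL
  motifs <- if (n > 0 && any(grepl("MOTIF=", fix[, "INFO"]))) {
    unname(vcfR::extract.info(vcf, element = "MOTIF"))
  } else rep(NA_character_, n)
  warned_samples <- character()

  for (i in seq_len(n)) {
    chrom <- fix[i, "CHROM"]
    src <- resolve_feature(store, chrom, required = FALSE)
    if (is.na(src)) {
      wc$add(i, paste0("CHROM '", chrom, "' not in store; record skipped"))
      next
    }
    pos <- as.integer(fix[i, "POS"])
    ref <- fix[i, "REF"]
    alt <- fix[i, "ALT"]
    vid <- fix[i, "ID"]
    nm <- if (!is.na(vid) && vid != ".") vid else
      sprintf("%s_%s_%d", marker_type, chrom, pos)
    so <- if (marker_type == "SNP") TX_SO_TYPES[["SNP"]] else
      TX_SO_TYPES[["microsatellite"]]
    org <- store$tables$feature$organism_id[store$tables$feature$feature_id == src]
    upsert_feature(store, nm, so, org)
    add_location(store, nm, src, fmin = pos - 1L, fmax = pos - 1L + nchar(ref))
    mid <- add_marker(store, nm, marker_type,
                      motif = if (marker_type == "SSR") motifs[i] else NA_character_,
                      ref_allele = if (marker_type == "SNP") ref else NA_character_,
                      alt_alleles = if (marker_type == "SNP") alt else NA_character_)
    alleles <- c(ref, if (!is.na(alt)) strsplit(alt, ",", fixed = TRUE)[[1]])
    for (s in samples) {
      gname <- gmap[[s]] %||% NA_character_
      gid <- if (!is.na(gname)) resolve_genotype(store, gname, required = FALSE) else
        NA_integer_
      if (is.na(gid)) {
        if (!s %in% warned_samples) {
          warned_samples <- c(warned_samples, s)
          wc$add(i, paste0("sample '", s, "' has no stored genotype; alleles skipped"))
        }
        next
      }
      call <- gt[i, s]
      if (is.na(call) || grepl("\\.", call)) next
      idx <- as.integer(strsplit(call, "[/|]")[[1]]) + 1L
      if (any(is.na(idx)) || any(idx > length(alleles))) next
      add_allele(store, mid, gid, paste(alleles[idx], collapse = "/"))
    }
    loaded <- loaded + 1L
  }
  audit(store, "load_vcf_markers", path)
  new_load_report(n, loaded, n - loaded, wc$tbl())
}

#' Load a generic association table
#'
#' Two- or three-column TAB/CSV files as the application's bulk path for
#' relationships the standard formats do not carry:
#' * `feature_cv`: feature, term — a manual term annotation per row;
#' * `feature_library`: feature, library name, value — a raw-count
#'   expression value per row;
#' * `feature_feature`: subject, predicate, object — a feature relationship.
#' A header row is auto-detected and skipped. Rows with unresolvable names
#' are skipped with a warning.
#'
#' @param store A `tx_store`.
#' @param path Table file; delimiter (TAB vs comma) is auto-detected.
#' @param kind One of `"feature_cv"`, `"feature_library"`,
#'   `"feature_feature"`.
#' @return A `tx_load_report`.
#' @export
load_association_table <- function(store, path,
                                   kind = c("feature_cv", "feature_library",
                                            "feature_feature")) {
  kind <- match.arg(kind)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^#", lines)
  idx <- which(keep)
  if (!length(idx)) return(new_load_report(0L, 0L, 0L))
  delim <- if (grepl("\t", lines[[idx[1]]])) "\t" else ","
  split_row <- function(i) trimws(strsplit(lines[[i]], delim, fixed = TRUE)[[1]])

  header_words <- c("feature", "name", "subject", "term", "term_id", "library",
                    "value", "predicate", "object", "target", "count")
  first <- split_row(idx[1])
  is_header <- any(tolower(first) %in% header_words) ||
    (kind == "feature_library" && length(first) >= 3 &&
       is.na(suppressWarnings(as.numeric(first[3]))))
  if (is_header) idx <- idx[-1]

  wc <- warn_collector()
  read <- length(idx); loaded <- 0L
  for (i in idx) {
    parts <- split_row(i)
    need <- if (kind == "feature_cv") 2L else 3L
    if (length(parts) < need) {
      wc$add(i, paste0("expected at least ", need, " columns; row skipped"))
      next
    }
    if (kind == "feature_cv") {
      fid <- resolve_feature(store, parts[1], required = FALSE)
      if (is.na(fid)) { wc$add(i, paste0("unknown feature '", parts[1], "'")); next }
      if (!term_resolves(store, parts[2])) {
        wc$add(i, paste0("term '", parts[2], "' not found")); next
      }
      add_term_annotation(store, fid, parts[2], source = "manual")
    } else if (kind == "feature_library") {
      fid <- resolve_feature(store, parts[1], required = FALSE)
      lib <- store$tables$seq_library
      lid <- lib$library_id[match(parts[2], lib$name)]
      val <- suppressWarnings(as.numeric(parts[3]))
      if (is.na(fid)) { wc$add(i, paste0("unknown feature '", parts[1], "'")); next }
      if (is.na(lid)) { wc$add(i, paste0("unknown library '", parts[2], "'")); next }
      if (is.na(val) || val < 0) { wc$add(i, "bad expression value"); next }
      add_expression_value(store, fid, lid, "raw_count", val)
    } else {
      s <- resolve_feature(store, parts[1], required = FALSE)
      o <- resolve_feature(store, parts[3], required = FALSE)
      if (is.na(s)) { wc$add(i, paste0("unknown feature '", parts[1], "'")); next }
      if (is.na(o)) { wc$add(i, paste0("unknown feature '", parts[3], "'")); next }
      add_relationship(store, s, parts[2], o)
    }
    loaded <- loaded + 1L
  }
  audit(store, "load_association_table", paste(kind, path))
  new_load_report(read, loaded, read - loaded, wc$tbl())
}
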