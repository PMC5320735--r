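#' The modular relational store
#'
#' Project data live in a single-file store organized after the Chado schema:
#' five core module groups (Sequence, General, Publication, Audit, Controlled
#' vocabularies) plus seven additional groups (Organism, Companalysis,
#' Phenotype, Strain, Genetics, Stock, Expression). Tables are typed tibbles;
#' every write path goes through the typed operations below, which enforce
#' referential integrity, and the persistent form is a deterministic
#' plain-text dump that doubles as the backup format. Coordinates are stored
#' interbase (0-based, half-open, Chado convention); 1-based inclusive
#' formats are converted at the I/O boundary.
#'
#' @name tx_store
NULL

# module group -> tables; the first five groups are the schema core
TX_MODULES <- list(
  "Sequence"                 = c("feature", "featureloc", "feature_relationship",
                                 "term_annotation"),
  "General"                  = c("dbxref_map"),
  "Publication"              = c("pub"),
  "Audit"                    = c("audit_log"),
  "Controlled vocabularies"  = c("cv", "cvterm", "cvterm_relationship"),
  "Organism"                 = c("organism"),
  "Companalysis"             = c("analysis", "blast_hit"),
  "Phenotype"                = c("phenotype"),
  "Strain"                   = c("strain"),
  "Genetics"                 = c("genotype", "genotype_attr", "marker", "allele"),
  "Stock"                    = c("stock"),
  "Expression"               = c("experiment", "experiment_term", "seq_library",
                                 "expression_value")
)
TX_CORE_MODULES <- c("Sequence", "General", "Publication", "Audit",
                     "Controlled vocabularies")

tx_schemas <- function() {
  list(
    organism = tibble::tibble(organism_id = integer(), genus = character(),
                              species = character(), common_name = character(),
                              abbreviation = character()),
    feature = tibble::tibble(feature_id = integer(), unique_name = character(),
                             display_name = character(), so_type = character(),
                             organism_id = integer(), residues = character(),
                             seqlen = integer(), analysis_id = integer()),
    featureloc = tibble::tibble(featureloc_id = integer(), feature_id = integer(),
                                srcfeature_id = integer(), fmin = integer(),
                                fmax = integer(), strand = integer(),
                                phase = integer()),
    feature_relationship = tibble::tibble(feature_relationship_id = integer(),
                                          subject_id = integer(),
                                          predicate = character(),
                                          object_id = integer(), rank = integer()),
    term_annotation = tibble::tibble(term_annotation_id = integer(),
                                     feature_id = integer(), term_id = character(),
                                     source = character(), analysis_id = integer()),
    dbxref_map = tibble::tibble(dbxref_id = integer(), external_id = character(),
                                term_id = character()),
    pub = tibble::tibble(pub_id = integer(), title = character(),
                         reference = character()),
    audit_log = tibble::tibble(audit_id = integer(), timestamp = character(),
                               action = character(), detail = character()),
    analysis = tibble::tibble(analysis_id = integer(), program = character(),
                              version = character(), parameters = character(),
                              timestamp = character()),
    blast_hit = tibble::tibble(blast_hit_id = integer(), feature_id = integer(),
                               hit_accession = character(), description = character(),
                               e_value = double(), bit_score = double(),
                               identity_pct = double(), query_start = integer(),
                               query_end = integer(), db_name = character(),
                               analysis_id = integer()),
    phenotype = tibble::tibble(phenotype_id = integer(), name = character(),
                               term_id = character(), value = character()),
    strain = tibble::tibble(strain_id = integer(), name = character(),
                            organism_id = integer()),
    genotype = tibble::tibble(genotype_id = integer(), name = character()),
    genotype_attr = tibble::tibble(genotype_attr_id = integer(),
                                   genotype_id = integer(), term_id = character(),
                                   value = character()),
    marker = tibble::tibble(marker_id = integer(), feature_id = integer(),
                            marker_type = character(), motif = character(),
                            ref_allele = character(), alt_alleles = character()),
    allele = tibble::tibble(allele_id = integer(), marker_id = integer(),
                            genotype_id = integer(), value = character()),
    stock = tibble::tibble(stock_id = integer(), name = character(),
                           organism_id = integer()),
    experiment = tibble::tibble(experiment_id = integer(), name = character(),
                                genotype_id = integer()),
    experiment_term = tibble::tibble(experiment_term_id = integer(),
                                     experiment_id = integer(),
                                     term_id = character(), value = character()),
    seq_library = tibble::tibble(library_id = integer(), name = character(),
                                 experiment_id = integer(),
                                 replicate_index = integer(),
                                 total_reads = integer()),
    expression_value = tibble::tibble(expression_value_id = integer(),
                                      feature_id = integer(), library_id = integer(),
                                      measure = character(), value = double())
  )
}

TX_DUMP_VERSION <- "txforge-dump 1"

#' Create a fresh store
#'
#' Initializes an empty store at `path` (a single dump file) with all twelve
#' module groups present, and returns a live handle.
#'
#' @param path File path for the store; created by this call.
#' @param overwrite Replace an existing store? Default `FALSE`.
#' @return A `tx_store` handle.
#' @export
init_store <- function(path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    stop("a store already exists at '", path,
         "'; pass overwrite = TRUE to replace it", call. = FALSE)
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  store <- new_tx_store(path)
  audit(store, "init", path)
  tx_save(store)
  store
}

new_tx_store <- function(path = NA_character_) {
  store <- new.env(parent = emptyenv())
  store$path <- path
  store$tables <- tx_schemas()
  store$ontologies <- list()
  class(store) <- "tx_store"
  store
}

#' @export
print.tx_store <- function(x, ...) {
  cat(sprintf("<tx_store> %s\n",
              if (is.na(x$path)) "(in memory)" else x$path))
  cat(sprintf("  %d feature(s), %d annotation(s), %d marker(s), %d expression value(s), %d ontolog%s\n",
              nrow(x$tables$feature), nrow(x$tables$term_annotation),
              nrow(x$tables$marker), nrow(x$tables$expression_value),
              length(x$ontologies), if (length(x$ontologies) == 1) "y" else "ies"))
  invisible(x)
}

#' Module-group metadata
#'
#' The store's tables grouped into the five core and seven additional module
#' groups; this structure is queryable metadata, not just documentation.
#'
#' @param store A `tx_store` (optional; the grouping is schema-level).
#' @return Tibble with columns `module`, `core`, `table`.
#' @export
tx_modules <- function(store = NULL) {
  tibble::tibble(
    module = rep(names(TX_MODULES), lengths(TX_MODULES)),
    core = rep(names(TX_MODULES) %in% TX_CORE_MODULES, lengths(TX_MODULES)),
    table = unlist(TX_MODULES, use.names = FALSE)
  )
}

#' Read one store table as a tibble
#'
#' `cv`, `cvterm` and `cvterm_relationship` are materialized from the loaded
#' ontology graphs.
#'
#' @param store A `tx_store`.
#' @param name Table name (see [tx_modules()]).
#' @return A tibble.
#' @export
tx_table <- function(store, name) {
  if (name == "cv") {
    return(tibble::tibble(cv_id = seq_along(store$ontologies),
                          name = names(store$ontologies) %||% character()))
  }
  if (name == "cvterm") {
    return(dplyr::bind_rows(purrr::imap(store$ontologies, function(g, nm) {
      dplyr::mutate(g$terms[c("term_id", "name", "namespace", "is_obsolete")],
                    cv = nm, .before = 1)
    })) %||% tibble::tibble())
  }
  if (name == "cvterm_relationship") {
    return(dplyr::bind_rows(purrr::imap(store$ontologies, function(g, nm) {
      dplyr::mutate(g$relations, cv = nm, .before = 1)
    })) %||% tibble::tibble())
  }
  tbl <- store$tables[[name]]
  if (is.null(tbl)) stop("unknown table: ", name, call. = FALSE)
  tbl
}

next_id <- function(store, table) {
  idcol <- paste0(sub("^seq_library$", "library", table), "_id")
  ids <- store$tables[[table]][[idcol]]
  if (length(ids)) max(ids) + 1L else 1L
}

audit <- function(store, action, detail = "") {
  tbl <- store$tables$audit_log
  store$tables$audit_log <- dplyr::bind_rows(tbl, tibble::tibble(
    audit_id = if (nrow(tbl)) max(tbl$audit_id) + 1L else 1L,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    action = action, detail = as.character(detail)
  ))
  invisible(store)
}

#' Register an organism
#'
#' @param store A `tx_store`.
#' @param genus,species Binomial components; `(genus, species)` is unique and
#'   re-adding it returns the existing id.
#' @param common_name,abbreviation Optional strings.
#' @return The organism id (integer).
#' @export
add_organism <- function(store, genus, species, common_name = NA_character_,
                         abbreviation = NA_character_) {
  tbl <- store$tables$organism
  hit <- which(tbl$genus == genus & tbl$species == species)
  if (length(hit)) return(invisible(tbl$organism_id[hit[1]]))
  id <- next_id(store, "organism")
  store$tables$organism <- dplyr::bind_rows(tbl, tibble::tibble(
    organism_id = id, genus = genus, species = species,
    common_name = common_name, abbreviation = abbreviation))
  audit(store, "add_organism", paste(genus, species))
  invisible(id)
}

resolve_organism <- function(store, organism) {
  force(organism)  # may itself write to the store (lazy caller promises)
  tbl <- store$tables$organism
  if (is.numeric(organism)) {
    if (!organism %in% tbl$organism_id) {
      stop("unknown organism id: ", organism, call. = FALSE)
    }
    return(as.integer(organism))
  }
  hit <- which(paste(tbl$genus, tbl$species) == organism |
                 tbl$abbreviation %in% organism & !is.na(tbl$abbreviation))
  if (!length(hit)) stop("unknown organism: ", organism, call. = FALSE)
  tbl$organism_id[hit[1]]
}

resolve_feature <- function(store, feature, required = TRUE) {
  force(feature)
  tbl <- store$tables$feature
  id <- if (is.numeric(feature)) {
    if (feature %in% tbl$feature_id) as.integer(feature) else NA_integer_
  } else {
    tbl$feature_id[match(feature, tbl$unique_name)]
  }
  if (required && is.na(id)) {
    stop("unknown feature: ", feature, call. = FALSE)
  }
  id
}

# does a CURIE resolve against the loaded ontologies? Terms whose prefix
# matches no loaded ontology (e.g. EC numbers) are accepted as-is.
term_resolves <- function(store, term_id) {
  if (!length(store$ontologies)) return(TRUE)
  known <- unlist(lapply(store$ontologies, function(g) g$terms$term_id),
                  use.names = FALSE)
  if (term_id %in% known) return(TRUE)
  prefixes <- unique(sub(":.*$", "", known))
  !(sub(":.*$", "", term_id) %in% prefixes)
}

find_store_term <- function(store, term_id) {
  for (nm in names(store$ontologies)) {
    if (has_term(store$ontologies[[nm]], term_id)) return(nm)
  }
  NA_character_
}

#' Insert or update a feature
#'
#' The single write path for features. Upserting an existing `unique_name`
#' (within the organism) updates the stored record in place and keeps its id;
#' re-upserting identical content is a no-op.
#'
#' @param store A `tx_store`.
#' @param unique_name Stable identifier, unique per organism.
#' @param so_type Sequence Ontology CURIE typing the feature; must resolve in
#'   a loaded SO graph when one is loaded.
#' @param organism Organism id or `"Genus species"` string.
#' @param residues Optional nucleotide string; `seqlen` is derived from it.
#' @param display_name Optional human-readable name.
#' @param analysis_id Optional provenance [add_analysis()] id.
#' @return The feature id (integer).
#' @export
upsert_feature <- function(store, unique_name, so_type, organism,
                           residues = NULL, display_name = NA_character_,
                           analysis_id = NA_integer_) {
  org_id <- resolve_organism(store, organism)
  if (!term_resolves(store, so_type)) {
    stop("so_type does not resolve in the loaded ontologies: ", so_type,
         call. = FALSE)
  }
  seqlen <- if (is.null(residues) || is.na(residues)) NA_integer_ else
    nchar(residues)
  residues <- if (is.null(residues)) NA_character_ else residues
  tbl <- store$tables$feature
  hit <- which(tbl$unique_name == unique_name & tbl$organism_id == org_id)
  row <- tibble::tibble(
    feature_id = if (length(hit)) tbl$feature_id[hit[1]] else
      next_id(store, "feature"),
    unique_name = unique_name, display_name = display_name, so_type = so_type,
    organism_id = org_id, residues = residues, seqlen = seqlen,
    analysis_id = as.integer(analysis_id))
  if (length(hit)) {
    tbl[hit[1], ] <- row
    store$tables$feature <- tbl
  } else {
    store$tables$feature <- dplyr::bind_rows(tbl, row)
  }
  audit(store, "upsert_feature", unique_name)
  invisible(row$feature_id)
}

#' Relate two stored features
#'
#' @param store A `tx_store`.
#' @param subject,object Feature unique names or ids; must exist and differ.
#' @param predicate Relationship label (e.g. `part_of`, `derives_from`).
#' @param rank Ordering integer within identical triples' context.
#' @return The relationship id.
#' @export
add_relationship <- function(store, subject, predicate, object, rank = 0L) {
  s <- resolve_feature(store, subject)
  o <- resolve_feature(store, object)
  if (s == o) stop("a feature cannot relate to itself: ", subject, call. = FALSE)
  tbl <- store$tables$feature_relationship
  hit <- which(tbl$subject_id == s & tbl$predicate == predicate & tbl$object_id == o)
  if (length(hit)) return(invisible(tbl$feature_relationship_id[hit[1]]))
  id <- next_id(store, "feature_relationship")
  store$tables$feature_relationship <- dplyr::bind_rows(tbl, tibble::tibble(
    feature_relationship_id = id, subject_id = s, predicate = predicate,
    object_id = o, rank = as.integer(rank)))
  audit(store, "add_relationship", paste(subject, predicate, object))
  invisible(id)
}

#' Locate a feature on a source feature
#'
#' Coordinates are interbase (0-based half-open): a feature covering bases
#' 1..100 of its source is stored as `fmin = 0, fmax = 100`.
#'
#' @param store A `tx_store`.
#' @param feature,source_feature Feature names or ids.
#' @param fmin,fmax Interbase coordinates, `0 <= fmin <= fmax`, and
#'   `fmax <= seqlen(source)` when the source length is known.
#' @param strand `+1`, `-1` or `0`.
#' @param phase Optional CDS phase (0, 1, 2).
#' @return The location id.
#' @export
add_location <- function(store, feature, source_feature, fmin, fmax,
                         strand = 0L, phase = NA_integer_) {
  f <- resolve_feature(store, feature)
  src <- resolve_feature(store, source_feature)
  fmin <- as.integer(fmin); fmax <- as.integer(fmax)
  if (is.na(fmin) || is.na(fmax) || fmin < 0 || fmin > fmax) {
    stop("invalid interbase range [", fmin, ", ", fmax, ")", call. = FALSE)
  }
  src_len <- store$tables$feature$seqlen[store$tables$feature$feature_id == src]
  if (!is.na(src_len) && fmax > src_len) {
    stop("location end ", fmax, " exceeds source feature length ", src_len,
         call. = FALSE)
  }
  tbl <- store$tables$featureloc
  hit <- which(tbl$feature_id == f & tbl$srcfeature_id == src &
                 tbl$fmin == fmin & tbl$fmax == fmax)
  if (length(hit)) return(invisible(tbl$featureloc_id[hit[1]]))
  id <- next_id(store, "featureloc")
  store$tables$featureloc <- dplyr::bind_rows(tbl, tibble::tibble(
    featureloc_id = id, feature_id = f, srcfeature_id = src, fmin = fmin,
    fmax = fmax, strand = as.integer(strand), phase = as.integer(phase)))
  invisible(id)
}

#' Record a computational-analysis run
#'
#' @param store A `tx_store`.
#' @param program,version,parameters,timestamp Provenance fields; the tuple
#'   identifies one run and is deduplicated.
#' @return The analysis id.
#' @export
add_analysis <- function(store, program, version = "", parameters = "",
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  tbl <- store$tables$analysis
  hit <- which(tbl$program == program & tbl$version == version &
                 tbl$parameters == parameters & tbl$timestamp == timestamp)
  if (length(hit)) return(invisible(tbl$analysis_id[hit[1]]))
  id <- next_id(store, "analysis")
  store$tables$analysis <- dplyr::bind_rows(tbl, tibble::tibble(
    analysis_id = id, program = program, version = version,
    parameters = parameters, timestamp = timestamp))
  invisible(id)
}

add_blast_hit <- function(store, feature, hit_accession, description, e_value,
                          bit_score, identity_pct, query_start, query_end,
                          db_name = "", analysis_id = NA_integer_) {
  f <- resolve_feature(store, feature)
  stopifnot(e_value >= 0, query_start <= query_end)
  tbl <- store$tables$blast_hit
  row <- tibble::tibble(
    blast_hit_id = next_id(store, "blast_hit"), feature_id = f,
    hit_accession = hit_accession, description = description,
    e_value = as.double(e_value), bit_score = as.double(bit_score),
    identity_pct = as.double(identity_pct),
    query_start = as.integer(query_start), query_end = as.integer(query_end),
    db_name = db_name, analysis_id = as.integer(analysis_id))
  dup <- which(tbl$feature_id == f & tbl$hit_accession == hit_accession &
                 tbl$query_start == row$query_start &
                 tbl$query_end == row$query_end &
                 tbl$bit_score == row$bit_score)
  if (length(dup)) return(invisible(tbl$blast_hit_id[dup[1]]))
  store$tables$blast_hit <- dplyr::bind_rows(tbl, row)
  invisible(row$blast_hit_id)
}

#' Annotate a feature with an ontology term
#'
#' @param store A `tx_store`.
#' @param feature Feature name or id.
#' @param term_id Term CURIE; must resolve when its ontology is loaded.
#' @param source One of `blast2go`, `interproscan`, `manual`, `dbxref-mapped`.
#' @param analysis_id Optional provenance id.
#' @return The annotation id; `(feature, term_id, source)` is deduplicated.
#' @export
add_term_annotation <- function(store, feature, term_id,
                                source = "manual", analysis_id = NA_integer_) {
  f <- resolve_feature(store, feature)
  if (!term_resolves(store, term_id)) {
    stop("term does not resolve in the loaded ontologies: ", term_id,
         call. = FALSE)
  }
  tbl <- store$tables$term_annotation
  hit <- which(tbl$feature_id == f & tbl$term_id == term_id & tbl$source == source)
  if (length(hit)) return(invisible(tbl$term_annotation_id[hit[1]]))
  id <- next_id(store, "term_annotation")
  store$tables$term_annotation <- dplyr::bind_rows(tbl, tibble::tibble(
    term_annotation_id = id, feature_id = f, term_id = term_id, source = source,
    analysis_id = as.integer(analysis_id)))
  invisible(id)
}

#' Register a genotype (line) with ontology-described attributes
#'
#' @param store A `tx_store`.
#' @param name Unique genotype name.
#' @param attributes Optional tibble/data.frame with columns `term_id` and
#'   optionally `value`.
#' @return The genotype id.
#' @export
add_genotype <- function(store, name, attributes = NULL) {
  tbl <- store$tables$genotype
  hit <- which(tbl$name == name)
  id <- if (length(hit)) tbl$genotype_id[hit[1]] else {
    id2 <- next_id(store, "genotype")
    store$tables$genotype <- dplyr::bind_rows(tbl, tibble::tibble(
      genotype_id = id2, name = name))
    audit(store, "add_genotype", name)
    id2
  }
  if (!is.null(attributes) && nrow(attributes)) {
    for (i in seq_len(nrow(attributes))) {
      t <- attributes$term_id[i]
      if (!term_resolves(store, t)) {
        stop("genotype attribute term does not resolve: ", t, call. = FALSE)
      }
      v <- if ("value" %in% names(attributes)) as.character(attributes$value[i]) else
        NA_character_
      at <- store$tables$genotype_attr
      if (!any(at$genotype_id == id & at$term_id == t &
                 (is.na(at$value) & is.na(v) | !is.na(at$value) & !is.na(v) &
                    at$value == v))) {
        store$tables$genotype_attr <- dplyr::bind_rows(at, tibble::tibble(
          genotype_attr_id = next_id(store, "genotype_attr"),
          genotype_id = id, term_id = t, value = v))
      }
    }
  }
  invisible(id)
}

resolve_genotype <- function(store, genotype, required = TRUE) {
  force(genotype)
  tbl <- store$tables$genotype
  id <- if (is.numeric(genotype)) {
    if (genotype %in% tbl$genotype_id) as.integer(genotype) else NA_integer_
  } else tbl$genotype_id[match(genotype, tbl$name)]
  if (required && is.na(id)) stop("unknown genotype: ", genotype, call. = FALSE)
  id
}

add_marker <- function(store, feature, marker_type = c("SSR", "SNP"),
                       motif = NA_character_, ref_allele = NA_character_,
                       alt_alleles = NA_character_) {
  marker_type <- match.arg(marker_type)
  f <- resolve_feature(store, feature)
  if (marker_type == "SSR" && is.na(motif)) {
    warning("SSR marker without a motif: ",
            store$tables$feature$unique_name[
              store$tables$feature$feature_id == f], call. = FALSE)
  }
  tbl <- store$tables$marker
  hit <- which(tbl$feature_id == f)
  if (length(hit)) return(invisible(tbl$marker_id[hit[1]]))
  id <- next_id(store, "marker")
  store$tables$marker <- dplyr::bind_rows(tbl, tibble::tibble(
    marker_id = id, feature_id = f, marker_type = marker_type, motif = motif,
    ref_allele = ref_allele, alt_alleles = alt_alleles))
  invisible(id)
}

add_allele <- function(store, marker_id, genotype, value) {
  if (!marker_id %in% store$tables$marker$marker_id) {
    stop("unknown marker id: ", marker_id, call. = FALSE)
  }
  g <- resolve_genotype(store, genotype)
  tbl <- store$tables$allele
  hit <- which(tbl$marker_id == marker_id & tbl$genotype_id == g)
  if (length(hit)) {
    store$tables$allele$value[hit[1]] <- value
    return(invisible(tbl$allele_id[hit[1]]))
  }
  id <- next_id(store, "allele")
  store$tables$allele <- dplyr::bind_rows(tbl, tibble::tibble(
    allele_id = id, marker_id = as.integer(marker_id), genotype_id = g,
    value = value))
  invisible(id)
}

#' Load an ontology into the store
#'
#' @param store A `tx_store`.
#' @param x OBO file path, character lines, or an `ontology_graph`.
#' @param name Name under which the graph is stored (defaults to the graph's
#'   own name).
#' @return The `ontology_graph`, invisibly.
#' @export
load_ontology <- function(store, x, name = NULL) {
  g <- if (inherits(x, "ontology_graph")) x else parse_obo(x, name = name)
  nm <- name %||% g$ontology_name
  g$ontology_name <- nm
  store$ontologies[[nm]] <- g
  audit(store, "load_ontology", nm)
  invisible(g)
}

#' Fetch a loaded ontology graph
#'
#' @param store A `tx_store`.
#' @param name Ontology name; when `NULL` and exactly one graph is loaded,
#'   that graph is returned.
#' @return An `ontology_graph`.
#' @export
get_ontology <- function(store, name = NULL) {
  if (is.null(name)) {
    if (length(store$ontologies) == 1) return(store$ontologies[[1]])
    stop("store has ", length(store$ontologies),
         " ontologies loaded; name one of: ",
         paste(names(store$ontologies), collapse = ", "), call. = FALSE)
  }
  g <- store$ontologies[[name]]
  if (is.null(g)) stop("no ontology named '", name, "' is loaded", call. = FALSE)
  g
}

#' Delete an entity and everything that depends on it
#'
#' Cascade rules follow the schema: deleting a feature removes its locations
#' (as located feature or as source), relationships, annotations, BLAST hits,
#' expression values, markers (with their alleles); deleting a genotype
#' removes its attributes and alleles; deleting an experiment removes its
#' condition terms, libraries and their expression values; deleting a marker
#' removes its alleles.
#'
#' @param store A `tx_store`.
#' @param kind One of `"feature"`, `"genotype"`, `"experiment"`, `"marker"`,
#'   `"library"`.
#' @param identifier Unique name (or id) of the record.
#' @return Total number of records removed (including the entity itself).
#' @export
delete_entity <- function(store, kind, identifier) {
  removed <- 0L
  drop_rows <- function(table, keep) {
    n <- sum(!keep)
    store$tables[[table]] <- store$tables[[table]][keep, , drop = FALSE]
    n
  }
  if (kind == "feature") {
    fid <- resolve_feature(store, identifier)
    mk <- store$tables$marker
    marker_ids <- mk$marker_id[mk$feature_id == fid]
    removed <- removed +
      drop_rows("allele", !store$tables$allele$marker_id %in% marker_ids) +
      drop_rows("marker", !store$tables$marker$feature_id == fid) +
      drop_rows("featureloc", !(store$tables$featureloc$feature_id == fid |
                                  store$tables$featureloc$srcfeature_id == fid)) +
      drop_rows("feature_relationship",
                !(store$tables$feature_relationship$subject_id == fid |
                    store$tables$feature_relationship$object_id == fid)) +
      drop_rows("term_annotation", !store$tables$term_annotation$feature_id == fid) +
      drop_rows("blast_hit", !store$tables$blast_hit$feature_id == fid) +
      drop_rows("expression_value",
                !store$tables$expression_value$feature_id == fid) +
      drop_rows("feature", !store$tables$feature$feature_id == fid)
  } else if (kind == "genotype") {
    gid <- resolve_genotype(store, identifier)
    removed <- removed +
      drop_rows("allele", !store$tables$allele$genotype_id == gid) +
      drop_rows("genotype_attr", !store$tables$genotype_attr$genotype_id == gid) +
      drop_rows("genotype", !store$tables$genotype$genotype_id == gid)
    store$tables$experiment$genotype_id[
      store$tables$experiment$genotype_id %in% gid] <- NA_integer_
  } else if (kind == "experiment") {
    ex <- store$tables$experiment
    eid <- if (is.numeric(identifier)) as.integer(identifier) else
      ex$experiment_id[match(identifier, ex$name)]
    if (is.na(eid) || !eid %in% ex$experiment_id) {
      stop("unknown experiment: ", identifier, call. = FALSE)
    }
    lib_ids <- store$tables$seq_library$library_id[
      store$tables$seq_library$experiment_id == eid]
    removed <- removed +
      drop_rows("expression_value",
                !store$tables$expression_value$library_id %in% lib_ids) +
      drop_rows("seq_library", !store$tables$seq_library$experiment_id == eid) +
      drop_rows("experiment_term",
                !store$tables$experiment_term$experiment_id == eid) +
      drop_rows("experiment", !store$tables$experiment$experiment_id == eid)
  } else if (kind == "marker") {
    mid <- as.integer(identifier)
    if (!mid %in% store$tables$marker$marker_id) {
      stop("unknown marker id: ", identifier, call. = FALSE)
    }
    removed <- removed +
      drop_rows("allele", !store$tables$allele$marker_id == mid) +
      drop_rows("marker", !store$tables$marker$marker_id == mid)
  } else if (kind == "library") {
    sl <- store$tables$seq_library
    lid <- if (is.numeric(identifier)) as.integer(identifier) else
      sl$library_id[match(identifier, sl$name)]
    if (is.na(lid) || !lid %in% sl$library_id) {
      stop("unknown library: ", identifier, call. = FALSE)
    }
    removed <- removed +
      drop_rows("expression_value",
                !store$tables$expression_value$library_id == lid) +
      drop_rows("seq_library", !store$tables$seq_library$library_id == lid)
  } else {
    stop("unknown entity kind: ", kind, call. = FALSE)
  }
  audit(store, "delete", paste(kind, identifier))
  removed
}

# ---- backup / restore -------------------------------------------------------

esc_field <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x[is.na(x)] <- "\\N"
  x
}

unesc_field <- function(x) {
  out <- ifelse(x == "\\N", NA_character_, x)
  out <- gsub("\\n", "\n", out, fixed = TRUE)
  out <- gsub("\\t", "\t", out, fixed = TRUE)
  gsub("\\\\", "\\", out, fixed = TRUE)
}

serialize_tbl <- function(tbl) {
  cols <- lapply(tbl, function(col) esc_field(as.character(col)))
  header <- paste(names(tbl), collapse = "\t")
  if (!nrow(tbl)) return(header)
  c(header, do.call(paste, c(cols, sep = "\t")))
}

deserialize_tbl <- function(lines, prototype) {
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  out <- prototype
  if (length(lines) > 1) {
    cells <- strsplit(lines[-1], "\t", fixed = TRUE)
    mat <- lapply(seq_along(header), function(j) {
      # trailing empty cells are dropped by strsplit; NA is encoded "\\N"
      unesc_field(vapply(cells, function(r) if (j <= length(r)) r[[j]] else "",
                         character(1)))
    })
    names(mat) <- header
    df <- tibble::as_tibble(mat)
    for (nm in names(prototype)) {
      proto_col <- prototype[[nm]]
      df[[nm]] <- if (is.integer(proto_col)) as.integer(df[[nm]])
        else if (is.double(proto_col)) as.double(df[[nm]])
        else if (is.logical(proto_col)) as.logical(df[[nm]])
        else df[[nm]]
    }
    out <- df[names(prototype)]
  }
  out
}

ontology_to_sections <- function(g) {
  terms <- g$terms
  flat <- tibble::tibble(
    term_id = terms$term_id, name = terms$name, namespace = terms$namespace,
    definition = terms$definition, is_obsolete = terms$is_obsolete,
    synonyms = vapply(terms$synonyms, paste, character(1), collapse = "|"),
    xrefs = vapply(terms$xrefs, paste, character(1), collapse = "|"))
  c(paste0("### meta\t", paste(g$closure_predicates, collapse = "|")),
    "### terms", serialize_tbl(flat),
    "### relations", serialize_tbl(g$relations))
}

sections_to_ontology <- function(name, lines) {
  meta <- grep("^### meta\t", lines, value = TRUE)
  preds <- strsplit(sub("^### meta\t", "", meta[[1]]), "|", fixed = TRUE)[[1]]
  ti <- which(lines == "### terms")
  ri <- which(lines == "### relations")
  term_proto <- tibble::tibble(term_id = character(), name = character(),
                               namespace = character(), definition = character(),
                               is_obsolete = logical(), synonyms = character(),
                               xrefs = character())
  flat <- deserialize_tbl(lines[(ti + 1):(ri - 1)], term_proto)
  rel_proto <- tibble::tibble(subject_id = character(), predicate = character(),
                              object_id = character())
  rel <- deserialize_tbl(lines[(ri + 1):length(lines)], rel_proto)
  split_bar <- function(x) {
    lapply(x, function(s) if (is.na(s) || !nzchar(s)) character() else
      strsplit(s, "|", fixed = TRUE)[[1]])
  }
  terms <- tibble::tibble(
    term_id = flat$term_id, name = flat$name, namespace = flat$namespace,
    definition = flat$definition, is_obsolete = flat$is_obsolete,
    synonyms = split_bar(flat$synonyms), xrefs = split_bar(flat$xrefs))
  new_ontology_graph(name, terms, rel, preds)
}

#' Dump the store to its portable plain-text backup form
#'
#' The dump is deterministic (stable table and row order) and diffable, with
#' a version header; [restore()] of a backup is observationally equal to the
#' original store.
#'
#' @param store A `tx_store`.
#' @param path Optional file to write; when `NULL` the dump lines are
#'   returned.
#' @return Character vector of dump lines, invisibly when written to a file.
#' @export
backup <- function(store, path = NULL) {
  lines <- TX_DUMP_VERSION
  for (nm in names(tx_schemas())) {
    tbl <- store$tables[[nm]]
    idcol <- names(tbl)[1]
    tbl <- tbl[order(tbl[[idcol]]), , drop = FALSE]
    lines <- c(lines, paste0("## table ", nm), serialize_tbl(tbl))
  }
  for (nm in sort(names(store$ontologies))) {
    lines <- c(lines, paste0("## ontology ", nm),
               ontology_to_sections(store$ontologies[[nm]]))
  }
  lines <- c(lines, "## end-of-dump")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Restore a store from a backup dump
#'
#' Rejects truncated or version-mismatched dumps without touching `path`.
#'
#' @param dump Dump lines or a path to a dump file.
#' @param path Path the restored store should live at (written on success).
#' @return A `tx_store` handle.
#' @export
restore <- function(dump, path = NULL) {
  lines <- if (length(dump) == 1 && file.exists(dump)) {
    readLines(dump, warn = FALSE)
  } else as.character(dump)
  if (!length(lines) || lines[[1]] != TX_DUMP_VERSION) {
    stop("not a recognized store dump (version header mismatch)", call. = FALSE)
  }
  if (lines[[length(lines)]] != "## end-of-dump") {
    stop("dump is truncated (missing end-of-dump marker); nothing restored",
         call. = FALSE)
  }
  store <- new_tx_store(path %||% NA_character_)
  heads <- grep("^## ", lines)
  bounds <- c(heads, length(lines) + 1L)
  for (k in seq_along(heads)) {
    head_line <- lines[heads[k]]
    body <- if (heads[k] + 1L <= bounds[k + 1L] - 1L) {
      lines[seq(heads[k] + 1L, bounds[k + 1L] - 1L)]
    } else character()
    if (grepl("^## table ", head_line)) {
      nm <- sub("^## table ", "", head_line)
      proto <- tx_schemas()[[nm]]
      if (!is.null(proto) && length(body)) {
        store$tables[[nm]] <- deserialize_tbl(body, proto)
      }
    } else if (grepl("^## ontology ", head_line)) {
      nm <- sub("^## ontology ", "", head_line)
      store$ontologies[[nm]] <- sections_to_ontology(nm, body)
    }
  }
  if (!is.null(path)) tx_save(store)
  store
}

#' Persist a live store to its file
#'
#' @param store A `tx_store` with a path.
#' @return The store, invisibly.
#' @export
tx_save <- function(store) {
  if (is.na(store$path)) stop("store has no path; use backup()", call. = FALSE)
  backup(store, store$path)
  invisible(store)
}

#' Open an existing store file
#'
#' @param path Path written by [init_store()] or [tx_save()].
#' @return A `tx_store` handle bound to `path`.
#' @export
tx_open <- function(path) {
  if (!file.exists(path)) stop("no store at '", path, "'", call. = FALSE)
  restore(readLines(path, warn = FALSE), path = NULL) -> store
  store$path <- path
  store
}

#' One-row store overview
#'
#' @param x A `tx_store`.
#' @param ... Ignored.
#' @return A one-row tibble of table counts.
#' @export
glance.tx_store <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$tables$feature),
    n_relationships = nrow(x$tables$feature_relationship),
    n_locations = nrow(x$tables$featureloc),
    n_annotations = nrow(x$tables$term_annotation),
    n_blast_hits = nrow(x$tables$blast_hit),
    n_markers = nrow(x$tables$marker),
    n_genotypes = nrow(x$tables$genotype),
    n_experiments = nrow(x$tables$experiment),
    n_libraries = nrow(x$tables$seq_library),
    n_expression_values = nrow(x$tables$expression_value),
    n_ontologies = length(x$ontologies)
  )
}

#' Per-table row counts
#'
#' @param x A `tx_store`.
#' @param ... Ignored.
#' @return Tibble with `module`, `core`, `table`, `n_rows`.
#' @export
tidy.tx_store <- function(x, ...) {
  mods <- tx_modules()
  mods$n_rows <- vapply(mods$table, function(nm) nrow(tx_table(x, nm)),
                        integer(1), USE.NAMES = FALSE)
  mods
}
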