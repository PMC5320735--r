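# Independent oracles and small builders shared across tests.
# The closure oracle is brute-force boolean-matrix reachability and never
# touches the package's traversal code.

oracle_reach <- function(n, subj, obj) {
  reach <- matrix(FALSE, n, n)
  if (length(subj)) reach[cbind(subj, obj)] <- TRUE
  repeat {
    nxt <- reach | ((reach %*% reach) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

# random rooted DAG as OBO text (edges always point to lower index, so the
# graph is acyclic by construction); returns the parsed graph + oracle matrix
rand_dag <- function(n, seed, max_parents = 3) {
  withr::with_seed(seed, {
    subj <- integer(); obj <- integer()
    for (i in seq_len(n)[-1]) {
      ps <- sample.int(i - 1L, min(sample.int(max_parents, 1L), i - 1L))
      subj <- c(subj, rep(i, length(ps)))
      obj <- c(obj, ps)
    }
    id <- function(i) sprintf("RND:%04d", i)
    lines <- c("format-version: 1.2", "")
    for (i in seq_len(n)) {
      lines <- c(lines, "[Term]", paste0("id: ", id(i)),
                 paste0("name: node ", i))
      mine <- which(subj == i)
      for (k in mine) {
        pred <- if (k %% 3 == 0) "relationship: part_of " else "is_a: "
        lines <- c(lines, paste0(pred, id(obj[k])))
      }
      lines <- c(lines, "")
    }
    list(graph = parse_obo(lines, name = "rnd"),
         reach = oracle_reach(n, subj, obj),
         id = id, n = n)
  })
}

chain_graph <- function() {
  parse_obo(c("[Term]", "id: T:0", "name: t0", "",
              "[Term]", "id: T:1", "name: t1", "is_a: T:0", "",
              "[Term]", "id: T:2", "name: t2", "is_a: T:1"))
}

diamond_graph <- function() {
  parse_obo(c("[Term]", "id: D:A", "name: a", "",
              "[Term]", "id: D:B", "name: b", "is_a: D:A", "",
              "[Term]", "id: D:C", "name: c", "is_a: D:A", "",
              "[Term]", "id: D:D", "name: d", "is_a: D:B", "is_a: D:C"))
}

# minimal populated store: one organism, transcripts with residues
tiny_store <- function(n_tx = 3, len = 100) {
  store <- init_store(tempfile(fileext = ".txdb"))
  org <- add_organism(store, "Toyia", "exempli")
  withr::with_seed(42, {
    for (i in seq_len(n_tx)) {
      upsert_feature(store, sprintf("isotig%03d", i), "SO:0000149", org,
                     residues = paste(sample(c("A", "C", "G", "T"), len,
                                             replace = TRUE), collapse = ""))
    }
  })
  store
}

local_toy_project <- function(seed = 1, ...) {
  dir <- file.path(tempdir(), paste0("toyproj_", seed))
  if (!file.exists(file.path(dir, "ground_truth.json"))) {
    make_toy_project(fixture_spec(seed = seed, ...), dir)
  }
  dir
}

# one shared fully loaded store per test run (loading is the expensive step)
loaded_toy_store <- local({
  cache <- new.env()
  function(seed = 1) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) {
      dir <- local_toy_project(seed)
      cache[[key]] <- list(
        store = replay_project(dir),
        manifest = jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                       simplifyVector = TRUE),
        dir = dir)
    }
    cache[[key]]
  }
})
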