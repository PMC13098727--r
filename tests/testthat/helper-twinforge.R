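# Shared fixtures, all built in code at test time.

# A small catalog with one variable per domain plus an admin artifact.
small_catalog <- function() {
  variable_catalog(
    variable_metadata("bmi", "Body mass index", "biological", "continuous",
                      modifiable = TRUE),
    variable_metadata("activity", "Vigorous activity frequency", "behavioral",
                      "ordinal", scale_min = 1, scale_max = 6,
                      modifiable = TRUE),
    variable_metadata("worry", "Anxiety symptoms", "psychosocial",
                      "continuous", scale_min = 0, modifiable = TRUE),
    variable_metadata("income", "Household income (log)", "socioeconomic",
                      "continuous"),
    variable_metadata("rx_checklist", "Prescription medicine checklist",
                      "biological", "binary", proxy = TRUE),
    variable_metadata("interviewer_id", "Interviewer ID", "administrative",
                      "categorical")
  )
}

# Ontology fixture written to a temp file.
write_ontology_fixture <- function(path = tempfile(fileext = ".json"),
                                   concepts = NULL, triples = NULL) {
  if (is.null(concepts)) {
    concepts <- list(
      list(iri = "T:1", label = "Type2Diabetes", definition = "A disease."),
      list(iri = "T:2", label = "Obesity", definition = "Excess adiposity."),
      list(iri = "T:3", label = "Body mass index", definition = "kg/m2.")
    )
  }
  if (is.null(triples)) {
    triples <- list(
      list(subject = "T:1", predicate = "hasRiskFactor", object = "T:2"),
      list(subject = "T:2", predicate = "isIndexedBy", object = "T:3")
    )
  }
  jsonlite::write_json(list(concepts = concepts, triples = triples), path,
                       auto_unbox = TRUE)
  path
}

# Embedder whose vectors come from a fixed lookup table (orthogonality and
# similarity are then fully controlled by the test).
lookup_embedder <- function(table, dim) {
  structure(list(
    embedder_id = "lookup", dim = dim,
    embed = function(texts) {
      out <- t(vapply(texts, function(tx) {
        v <- table[[tx]]
        if (is.null(v)) v <- c(1, rep(0, dim - 1))
        v / sqrt(sum(v^2))
      }, numeric(dim)))
      rownames(out) <- NULL
      out
    }), class = "embedder")
}

# Backend returning a fixed score for every variable.
constant_backend <- function(score, classification = NULL, reasoning = "r") {
  if (is.null(classification)) {
    classification <- if (score >= 0.7) "Direct" else if (score >= 0.3)
      "Indirect" else "Unrelated"
  }
  stub_backend_keyword(function(name) list(relevance_score = score,
                                           classification = classification,
                                           reasoning = reasoning))
}

# Small complete synthetic panel for model tests.
tiny_panel <- function(n = 400, seed = 1, ...) {
  generate_cohort(cohort_spec(n_participants = n, seed = seed, ...))
}

# Brute-force AUC over all positive/negative pairs (independent oracle).
auc_bruteforce <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# Exhaustive optimal contiguous partition of sorted 1-D data into K blocks,
# by enumerating all boundary placements (independent oracle for fit_states).
contiguous_partition_sse <- function(x, K) {
  x <- sort(x)
  n <- length(x)
  sse_block <- function(seg) sum((seg - mean(seg))^2)
  best <- Inf
  cuts <- utils::combn(n - 1, K - 1)
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    s <- 0
    for (k in seq_len(K)) s <- s + sse_block(x[(b[k] + 1):b[k + 1]])
    if (s < best) best <- s
  }
  best
}
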