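#' Load ontology fixtures
#'
#' Reads one or more JSON ontology files, each with a `concepts` array
#' (objects with `iri`, `label`, optional `definition` and
#' `source_ontology`) and a `triples` array (objects with `subject`,
#' `predicate`, `object`). Triples whose subject or object does not resolve
#' to a loaded concept are collected as dangling rather than treated as
#' fatal.
#'
#' @param paths Character vector of JSON file paths.
#' @return An `ontology` object: list with data frames `concepts`,
#'   `triples`, and `dangling`.
#' @export
load_ontology <- function(paths) {
  concepts <- list(); triples <- list()
  for (path in paths) {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    for (i in seq_along(doc$concepts)) {
      cpt <- doc$concepts[[i]]
      if (is.null(cpt$iri) || is.null(cpt$label)) {
        stop("malformed concept record ", i, " in '", path,
             "': iri and label are required")
      }
      concepts[[length(concepts) + 1L]] <- data.frame(
        iri = cpt$iri, label = cpt$label,
        definition = if (is.null(cpt$definition)) "" else cpt$definition,
        source_ontology = if (is.null(cpt$source_ontology)) basename(path) else cpt$source_ontology,
        stringsAsFactors = FALSE)
    }
    for (i in seq_along(doc$triples)) {
      tr <- doc$triples[[i]]
      if (is.null(tr$subject) || is.null(tr$predicate) || is.null(tr$object)) {
        stop("malformed triple record ", i, " in '", path,
             "': subject, predicate, object are required")
      }
      triples[[length(triples) + 1L]] <- data.frame(
        subject_iri = tr$subject, predicate = tr$predicate,
        object_iri = tr$object, stringsAsFactors = FALSE)
    }
  }
  concepts <- if (length(concepts)) do.call(rbind, concepts) else
    data.frame(iri = character(), label = character(),
               definition = character(), source_ontology = character(),
               stringsAsFactors = FALSE)
  triples <- if (length(triples)) do.call(rbind, triples) else
    data.frame(subject_iri = character(), predicate = character(),
               object_iri = character(), stringsAsFactors = FALSE)
  if (anyDuplicated(concepts$iri)) {
    stop("duplicate concept iri across loaded ontologies: ",
         paste(unique(concepts$iri[duplicated(concepts$iri)]), collapse = ", "))
  }
  dang <- !(triples$subject_iri %in% concepts$iri) |
    !(triples$object_iri %in% concepts$iri)
  structure(list(concepts = concepts,
                 triples = triples[!dang, , drop = FALSE],
                 dangling = triples[dang, , drop = FALSE]),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("Ontology: %d concepts, %d triples (%d dangling)\n",
              nrow(x$concepts), nrow(x$triples), nrow(x$dangling)))
  invisible(x)
}

## FNV-1a style rolling hash of a character vector of tokens -> integer in
## [0, m). Pure integer arithmetic in doubles, deterministic across platforms.
token_hash <- function(tokens, m, salt = 0) {
  ## modulus < 2^26 keeps every intermediate product exactly representable
  vapply(tokens, function(tok) {
    h <- (2166136261 + salt) %% 67108859
    for (cp in utf8ToInt(tok)) {
      h <- (bitwXor(as.integer(h), as.integer(cp)) * 16777619) %% 67108859
    }
    h %% m
  }, numeric(1), USE.NAMES = FALSE)
}

#' Deterministic feature-hashing text embedder
#'
#' Maps text to a fixed-length unit vector by hashing lower-cased character
#' n-grams into signed buckets. Deterministic per text with no random state,
#' so identical texts always embed identically and cosine similarity of a
#' text with itself is exactly 1. Satisfies the embedder contract that a
#' sentence-transformer adapter would also satisfy (text to unit-norm
#' fixed-length vector).
#'
#' @param dim Embedding dimension.
#' @param ngram n-gram length in characters.
#' @return An `embedder` object with fields `embedder_id`, `dim`, and
#'   `embed(texts)` returning a `length(texts) x dim` matrix of unit rows.
#' @export
hash_embedder <- function(dim = 64, ngram = 3) {
  embed <- function(texts) {
    out <- matrix(0, nrow = length(texts), ncol = dim)
    for (i in seq_along(texts)) {
      txt <- tolower(texts[[i]])
      txt <- gsub("[^a-z0-9 ]+", " ", txt)
      txt <- paste0(" ", gsub(" +", " ", trimws(txt)), " ")
      nc <- nchar(txt)
      if (nc >= ngram) {
        grams <- substring(txt, seq_len(nc - ngram + 1),
                           seq_len(nc - ngram + 1) + ngram - 1)
        idx <- token_hash(grams, dim) + 1
        sgn <- ifelse(token_hash(grams, 2, salt = 77) == 0, 1, -1)
        for (g in seq_along(grams)) {
          out[i, idx[g]] <- out[i, idx[g]] + sgn[g]
        }
      }
      nrm <- sqrt(sum(out[i, ]^2))
      if (nrm == 0) { out[i, 1] <- 1 } else { out[i, ] <- out[i, ] / nrm }
    }
    out
  }
  structure(list(embedder_id = sprintf("hash-ngram%d-%d", ngram, dim),
                 dim = dim, embed = embed),
            class = "embedder")
}

#' Build an embedding index over ontology concept labels
#'
#' @param ontology An `ontology` (or a concepts data frame).
#' @param embedder An embedder satisfying the text-to-unit-vector contract,
#'   e.g. [hash_embedder()].
#' @return An `embedding_index`: unit-norm vectors keyed by concept iri, plus
#'   the concept and triple tables needed to assemble retrieval contexts.
#' @export
build_index <- function(ontology, embedder = hash_embedder()) {
  concepts <- if (inherits(ontology, "ontology")) ontology$concepts else ontology
  triples <- if (inherits(ontology, "ontology")) ontology$triples else
    data.frame(subject_iri = character(), predicate = character(),
               object_iri = character(), stringsAsFactors = FALSE)
  vectors <- embedder$embed(concepts$label)
  if (!is.matrix(vectors) || ncol(vectors) != embedder$dim ||
      nrow(vectors) != nrow(concepts)) {
    stop("embedder returned wrong dimensionality (expected ",
         nrow(concepts), " x ", embedder$dim, ")")
  }
  nrm <- sqrt(rowSums(vectors^2))
  if (nrow(vectors) > 0 && any(abs(nrm - 1) > 1e-6)) {
    stop("embedder contract violated: vectors must be unit norm")
  }
  rownames(vectors) <- concepts$iri
  structure(list(embedder_id = embedder$embedder_id, embedder = embedder,
                 vectors = vectors, concepts = concepts, triples = triples),
            class = "embedding_index")
}

#' Retrieve the top-k ontology concepts for a variable
#'
#' Embeds the variable text (name and label concatenated, configurable),
#' scores cosine similarity against every indexed concept, keeps matches at
#' or above the threshold, sorts descending (ties broken by lexicographic
#' iri), truncates to `k`, and attaches the triples touching each kept
#' concept together with its definition as explanation text. Defaults mirror
#' the retrieval setting the framework was designed around: top-k = 5 above
#' a similarity threshold of 0.3.
#'
#' @param variable One catalog row (see [variable_metadata()]).
#' @param index An `embedding_index`; `NULL` or an empty index yields an
#'   empty context.
#' @param k Maximum number of matches (>= 1).
#' @param threshold Minimum cosine similarity in `[-1, 1]`.
#' @param text_fields Which variable fields to embed.
#' @return A `retrieval_context`.
#' @export
retrieve_concepts <- function(variable, index, k = 5, threshold = 0.3,
                              text_fields = c("name", "label")) {
  stopifnot(k >= 1, threshold >= -1, threshold <= 1)
  text <- paste(unlist(variable[1, text_fields]), collapse = " ")
  empty <- structure(list(variable = variable, query_text = text,
                          matches = list(),
                          concepts = if (is.null(index)) NULL else index$concepts),
                     class = "retrieval_context")
  if (is.null(index) || nrow(index$vectors) == 0) return(empty)
  v <- as.vector(index$embedder$embed(text))
  sims <- as.vector(index$vectors %*% v)
  keep <- which(sims >= threshold)
  if (!length(keep)) return(empty)
  iris <- rownames(index$vectors)[keep]
  ord <- order(-sims[keep], iris)
  keep <- keep[ord][seq_len(min(k, length(ord)))]
  matches <- lapply(keep, function(i) {
    iri <- rownames(index$vectors)[i]
    cpt <- index$concepts[index$concepts$iri == iri, , drop = FALSE]
    tr <- index$triples[index$triples$subject_iri == iri |
                          index$triples$object_iri == iri, , drop = FALSE]
    list(concept = cpt, similarity = sims[i], triples = tr,
         explanation = cpt$definition)
  })
  structure(list(variable = variable, query_text = text, matches = matches,
                 concepts = index$concepts),
            class = "retrieval_context")
}

render_triple <- function(tr, concepts) {
  lab <- function(iri) {
    i <- match(iri, concepts$iri)
    if (is.na(i)) iri else concepts$label[i]
  }
  sprintf("%s → %s → %s", lab(tr$subject_iri), tr$predicate,
          lab(tr$object_iri))
}

#' Render a retrieval context as the structured prompt block
#'
#' Deterministic layout: one section per match with the concept label, IRI,
#' similarity to three decimals, its triples rendered
#' `Subject -> predicate -> Object`, and the explanation text. An empty
#' context renders a fixed sentinel block.
#'
#' @param ctx A `retrieval_context`.
#' @return A single character string.
#' @export
format_context <- function(ctx) {
  stopifnot(inherits(ctx, "retrieval_context"))
  if (!length(ctx$matches)) {
    return("Ontology context:\n(no ontology matches above the similarity threshold)")
  }
  lookup <- if (is.null(ctx$concepts)) {
    data.frame(iri = character(), label = character())
  } else ctx$concepts
  blocks <- vapply(ctx$matches, function(m) {
    trs <- if (nrow(m$triples)) {
      paste(vapply(seq_len(nrow(m$triples)), function(i) {
        paste0("  - ", render_triple(m$triples[i, ], lookup))
      }, character(1)), collapse = "\n")
    } else "  - (no relations)"
    paste0("- Concept: ", m$concept$label, " [", m$concept$iri, "]",
           " (similarity ", sprintf("%.3f", m$similarity), ")\n",
           "  Relations:\n", trs, "\n",
           "  Explanation: ",
           if (nzchar(m$explanation)) m$explanation else "(none)")
  }, character(1))
  paste0("Ontology context:\n", paste(blocks, collapse = "\n"))
}
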