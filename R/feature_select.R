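#' Language-model backend contract
#'
#' A backend is any object exposing `invoke(prompt, temperature)` returning
#' raw response text, plus a `backend_id`. The relevance agent only depends
#' on this contract; shipped stubs keep the pipeline deterministic, and an
#' adapter around a live chat-completions API satisfies the same contract.
#'
#' @param invoke Function `(prompt, temperature) -> character(1)`.
#' @param backend_id Name recorded in logs.
#' @return An `llm_backend`.
#' @export
llm_backend <- function(invoke, backend_id) {
  stopifnot(is.function(invoke), is.character(backend_id))
  structure(list(invoke = invoke, backend_id = backend_id),
            class = "llm_backend")
}

#' Scripted stub backend
#'
#' Returns the supplied responses in order (the last response repeats once
#' the queue is exhausted). Used to exercise the parse/requery/exclude
#' control flow deterministically.
#'
#' @param responses Character vector of raw response texts.
#' @return An `llm_backend`.
#' @export
stub_backend_scripted <- function(responses) {
  stopifnot(length(responses) >= 1)
  env <- new.env(parent = emptyenv())
  env$i <- 0L
  llm_backend(function(prompt, temperature) {
    env$i <- env$i + 1L
    responses[[min(env$i, length(responses))]]
  }, backend_id = "stub-scripted")
}

decision_json <- function(score, classification, reasoning) {
  jsonlite::toJSON(list(relevance_score = score,
                        classification = classification,
                        reasoning = reasoning),
                   auto_unbox = TRUE, digits = NA)
}

#' Keyword stub backend scoring by variable name
#'
#' Parses the variable name out of the prompt and maps it through
#' `score_fun`, which must return `list(relevance_score=, classification=,
#' reasoning=)`. Deterministic given the prompt.
#'
#' @param score_fun Function of the variable name.
#' @return An `llm_backend`.
#' @export
stub_backend_keyword <- function(score_fun) {
  llm_backend(function(prompt, temperature) {
    m <- regmatches(prompt, regexec("Variable name: ([^\n]+)", prompt))[[1]]
    name <- if (length(m) == 2) m[2] else ""
    d <- score_fun(name)
    as.character(decision_json(d$relevance_score, d$classification, d$reasoning))
  }, backend_id = "stub-keyword")
}

#' Domain-aware stub backend
#'
#' Scores variables by their catalog domain tag: administrative variables
#' score far below the exclusion threshold, downstream proxies just below
#' it, and substantive domains well above. This emulates an agent whose
#' ontology-grounded reasoning screens out artifacts and proxies, and powers
#' the semantic-audit comparisons against the statistical baselines.
#'
#' @param catalog A [variable_catalog()].
#' @param domain_scores Named scores per domain.
#' @return An `llm_backend`.
#' @export
stub_backend_domain <- function(catalog,
                                domain_scores = c(biological = 0.85,
                                                  behavioral = 0.75,
                                                  psychosocial = 0.65,
                                                  socioeconomic = 0.55,
                                                  administrative = 0.05)) {
  stub_backend_keyword(function(name) {
    i <- match(name, catalog$name)
    if (is.na(i)) {
      return(list(relevance_score = 0.5, classification = "Indirect",
                  reasoning = "Unknown variable; neutral relevance."))
    }
    score <- unname(domain_scores[[catalog$domain[i]]])
    if (isTRUE(catalog$proxy[i])) score <- 0.2
    cls <- if (score >= 0.7) "Direct" else if (score >= 0.3) "Indirect" else "Unrelated"
    list(relevance_score = score, classification = cls,
         reasoning = sprintf("%s-domain variable%s.", catalog$domain[i],
                             if (isTRUE(catalog$proxy[i])) " flagged as downstream proxy" else ""))
  })
}

default_rubric <- function() {
  paste("Scoring rubric: 0.0-0.29 unrelated or administrative artifact;",
        "0.3-0.69 indirectly relevant (psychosocial, socioeconomic, or",
        "behavioral pathway); 0.7-1.0 directly relevant established risk",
        "factor. Downstream proxies of the outcome (e.g. disease-specific",
        "medication use) must not be scored as upstream determinants.")
}

system_instruction <- function() {
  paste("You are a biomedical relevance-classification agent. Assess how",
        "relevant the survey variable below is for predicting future",
        "type 2 diabetes onset, using the ontology context provided.")
}

#' Assemble the relevance-classification prompt
#'
#' Deterministic concatenation of the fixed system instruction, the variable
#' metadata, the rendered ontology context block, the scoring rubric, and
#' the required-JSON-schema statement.
#'
#' @param variable One catalog row.
#' @param ctx_block Rendered context from [format_context()].
#' @param rubric Scoring rubric text.
#' @return Prompt text.
#' @export
build_prompt <- function(variable, ctx_block, rubric = default_rubric()) {
  paste0(system_instruction(), "\n\n",
         "Variable name: ", variable$name, "\n",
         "Variable label: ", variable$label, "\n",
         "Domain: ", variable$domain, "\n",
         "Type: ", variable$dtype, "\n\n",
         ctx_block, "\n\n",
         rubric, "\n\n",
         "Return valid JSON with exactly these fields: ",
         '{"relevance_score": number in [0,1], ',
         '"classification": "Direct"|"Indirect"|"Unrelated", ',
         '"reasoning": string}.')
}

parse_decision <- function(raw) {
  parsed <- tryCatch(jsonlite::fromJSON(raw), error = function(e) NULL)
  if (is.null(parsed) || !is.list(parsed)) {
    return(list(ok = FALSE, reason = "response is not valid JSON"))
  }
  s <- parsed$relevance_score
  cl <- parsed$classification
  if (!is.numeric(s) || length(s) != 1 || is.na(s) || s < 0 || s > 1) {
    return(list(ok = FALSE, reason = "relevance_score missing or outside [0,1]"))
  }
  if (!is.character(cl) || length(cl) != 1 ||
      !cl %in% c("Direct", "Indirect", "Unrelated")) {
    return(list(ok = FALSE, reason = "classification not in {Direct, Indirect, Unrelated}"))
  }
  reasoning <- if (is.character(parsed$reasoning)) parsed$reasoning else ""
  list(ok = TRUE, score = as.numeric(s), classification = cl,
       reasoning = reasoning)
}

new_agent_log <- function() {
  env <- new.env(parent = emptyenv())
  env$records <- list()
  env
}

log_invocation <- function(log, variable, attempt, prompt, raw, parsed_ok,
                           backend_id) {
  if (is.null(log)) return(invisible(NULL))
  log$records[[length(log$records) + 1L]] <- list(
    variable = variable, attempt = attempt,
    prompt_digest = text_digest(prompt),
    raw_response = raw, parsed_ok = parsed_ok,
    backend_id = backend_id, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"))
  invisible(NULL)
}

#' Classify one variable's relevance with the bounded agent loop
#'
#' Retrieves ontology context, queries the backend once at the configured
#' temperature, and validates the response (JSON schema, score range,
#' classification enum, score/class band consistency). On an invalid
#' response, an inconsistent band, or a score below the exclusion threshold,
#' the variable is requeried exactly once with expanded ontology context
#' (retrieval k doubled); a second failure or sub-threshold score marks the
#' decision excluded. At most two backend invocations per variable, ever.
#'
#' @param variable One catalog row.
#' @param index An `embedding_index` (or `NULL` for no ontology context).
#' @param backend An [llm_backend()].
#' @param k Retrieval top-k for the first attempt.
#' @param sim_threshold Retrieval similarity threshold.
#' @param temperature Sampling temperature passed to the backend.
#' @param threshold Exclusion threshold on the relevance score.
#' @param rubric Scoring rubric text.
#' @param log Internal invocation log environment (optional).
#' @return A `relevance_decision`.
#' @export
classify_variable <- function(variable, index, backend, k = 5,
                              sim_threshold = 0.3, temperature = 0.3,
                              threshold = 0.3, rubric = default_rubric(),
                              log = NULL) {
  attempt_once <- function(k_now) {
    ctx <- retrieve_concepts(variable, index, k = k_now,
                             threshold = sim_threshold)
    prompt <- build_prompt(variable, format_context(ctx), rubric)
    raw <- backend$invoke(prompt, temperature)
    parsed <- parse_decision(raw)
    log_invocation(log, variable$name, NA, prompt, raw, parsed$ok,
                   backend$backend_id)
    list(prompt = prompt, raw = raw, parsed = parsed)
  }
  acceptable <- function(parsed) {
    parsed$ok && parsed$score >= threshold &&
      critic_check_decision_fields(parsed$score, parsed$classification)$verdict == "pass"
  }
  a1 <- attempt_once(k)
  if (acceptable(a1$parsed)) {
    return(new_decision(variable$name, a1$parsed, requery_count = 0L,
                        excluded = FALSE, prompt = a1$prompt))
  }
  a2 <- attempt_once(2 * k)
  if (acceptable(a2$parsed)) {
    return(new_decision(variable$name, a2$parsed, requery_count = 1L,
                        excluded = FALSE, prompt = a2$prompt))
  }
  p <- if (a2$parsed$ok) a2$parsed else list(score = NA_real_,
                                             classification = NA_character_,
                                             reasoning = "invalid response on both attempts")
  new_decision(variable$name, p, requery_count = 1L, excluded = TRUE,
               prompt = a2$prompt)
}

new_decision <- function(name, parsed, requery_count, excluded, prompt) {
  structure(list(variable = name,
                 relevance_score = parsed$score,
                 classification = parsed$classification,
                 reasoning = parsed$reasoning,
                 requery_count = requery_count,
                 excluded = excluded,
                 context_digest = text_digest(prompt)),
            class = "relevance_decision")
}

#' Agent-based feature selection over a catalog
#'
#' Processes variables in fixed catalog order in batches, classifies each
#' with [classify_variable()], drops excluded decisions, ranks the remainder
#' by relevance score descending (ties keep catalog order), and truncates to
#' `top_k`. Deterministic with a stub backend.
#'
#' @param catalog A [variable_catalog()].
#' @param index An `embedding_index` or `NULL`.
#' @param backend An [llm_backend()].
#' @param top_k Number of features retained (default 200).
#' @param batch_size Variables per processing batch (default 40).
#' @param log_path Optional JSONL path; one record per backend invocation.
#' @param ... Passed to [classify_variable()].
#' @return A `feature_ranking` data frame (variable, score, classification,
#'   reasoning, requery_count) with the invocation log and all decisions as
#'   attributes.
#' @export
select_features <- function(catalog, index, backend, top_k = 200,
                            batch_size = 40, log_path = NULL, ...) {
  stopifnot(nrow(catalog) > 0)
  log <- new_agent_log()
  decisions <- vector("list", nrow(catalog))
  batches <- split(seq_len(nrow(catalog)),
                   ceiling(seq_len(nrow(catalog)) / batch_size))
  for (b in batches) {
    for (i in b) {
      decisions[[i]] <- classify_variable(catalog[i, , drop = FALSE], index,
                                          backend, log = log, ...)
    }
  }
  kept <- decisions[!vapply(decisions, function(d) d$excluded, logical(1))]
  scores <- vapply(kept, function(d) d$relevance_score, numeric(1))
  ord <- order(-scores)                      # stable: ties keep catalog order
  ord <- ord[seq_len(min(top_k, length(ord)))]
  ranking <- data.frame(
    variable = vapply(kept, function(d) d$variable, character(1))[ord],
    score = scores[ord],
    classification = vapply(kept, function(d) d$classification, character(1))[ord],
    reasoning = vapply(kept, function(d) d$reasoning, character(1))[ord],
    requery_count = vapply(kept, function(d) d$requery_count, integer(1))[ord],
    stringsAsFactors = FALSE)
  if (!is.null(log_path)) {
    con <- file(log_path, open = "w")
    on.exit(close(con))
    for (rec in log$records) {
      writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE)), con)
    }
  }
  structure(ranking,
            class = c("feature_ranking", "data.frame"),
            selection_method = "agent", k = top_k,
            decisions = decisions, log = log$records,
            n_invocations = length(log$records))
}

#' Statistical baseline feature selection (Lasso / mutual information)
#'
#' Lasso ranks features by absolute coefficient of an L1-regularized
#' logistic regression, taking the largest penalty on the glmnet path with
#' at least `k` non-zero coefficients (or the smallest penalty if none
#' reaches `k`). Mutual information ranks by the plug-in MI (nats) between
#' each feature (continuous features binned into equal-frequency deciles)
#' and the binary outcome. Both are deterministic at a fixed seed.
#'
#' @param X Numeric feature matrix (see [build_design()]).
#' @param y Binary outcome vector.
#' @param method `"lasso"` or `"mutual_information"`.
#' @param k Number of features retained.
#' @param seed Seed (default 42) for deterministic comparisons.
#' @return A `feature_ranking` data frame with columns variable and score.
#' @export
baseline_select <- function(X, y, method = c("lasso", "mutual_information"),
                            k = 200, seed = 42) {
  method <- match.arg(method)
  stopifnot(is.matrix(X), length(y) == nrow(X))
  if (k > ncol(X)) {
    warning("k exceeds feature count; returning all ", ncol(X), " features")
    k <- ncol(X)
  }
  set.seed(seed)
  if (method == "lasso") {
    fit <- glmnet::glmnet(X, y, family = "binomial", standardize = TRUE)
    nz <- fit$df
    pick <- which(nz >= k)[1]
    if (is.na(pick)) pick <- length(fit$lambda)
    beta <- abs(as.numeric(fit$beta[, pick]))
    names(beta) <- rownames(fit$beta)
    scores <- beta
  } else {
    scores <- apply(X, 2, function(x) mutual_information_binned(x, y))
  }
  ord <- order(-scores)
  ord <- ord[seq_len(k)]
  structure(data.frame(variable = colnames(X)[ord], score = unname(scores[ord]),
                       stringsAsFactors = FALSE),
            class = c("feature_ranking", "data.frame"),
            selection_method = method, k = k)
}

#' Plug-in mutual information between a feature and a discrete outcome
#'
#' Continuous features are discretized into at most `bins` equal-frequency
#' bins; MI is the plug-in estimate in nats. Under independence the estimate
#' converges to 0 (upward bias of order (|X|-1)(|Y|-1)/(2n)).
#'
#' @param x Feature vector.
#' @param y Discrete outcome vector.
#' @param bins Maximum number of bins for continuous features.
#' @return MI estimate in nats.
#' @export
mutual_information_binned <- function(x, y, bins = 10) {
  ux <- unique(x)
  if (length(ux) > bins) {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                          na.rm = TRUE))
    x <- cut(x, breaks = br, include.lowest = TRUE)
  }
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  }
  mi
}

#' Semantic audit of a feature ranking
#'
#' Maps each selected variable (encoded design columns are traced back to
#' their source variable) onto one of three audit categories via its catalog
#' tags: `noise_administrative` (administrative domain), `proxy_downstream`
#' (proxy flag), or `target_relevant` (everything else). Given a named list
#' of rankings, returns the per-method comparison table.
#'
#' @param ranking A `feature_ranking`, or a named list of them.
#' @param catalog A [variable_catalog()].
#' @return An `audit_report` with per-category counts (single ranking) or
#'   the comparison data frame (list of rankings).
#' @export
semantic_audit <- function(ranking, catalog) {
  if (is.list(ranking) && !is.data.frame(ranking)) {
    rows <- lapply(names(ranking), function(nm) {
      a <- semantic_audit(ranking[[nm]], catalog)
      data.frame(method = nm, n_selected = a$n,
                 target_relevant = a$counts[["target_relevant"]],
                 noise_administrative = a$counts[["noise_administrative"]],
                 proxy_downstream = a$counts[["proxy_downstream"]],
                 stringsAsFactors = FALSE)
    })
    return(structure(do.call(rbind, rows), class = c("audit_report", "data.frame")))
  }
  vars <- source_variable(ranking$variable, catalog)
  unknown <- unique(ranking$variable[is.na(vars)])
  if (length(unknown)) {
    stop("ranked variable(s) not present in catalog: ",
         paste(unknown, collapse = ", "))
  }
  dom <- catalog$domain[match(vars, catalog$name)]
  prox <- catalog$proxy[match(vars, catalog$name)]
  category <- ifelse(dom == "administrative", "noise_administrative",
                     ifelse(prox, "proxy_downstream", "target_relevant"))
  counts <- c(target_relevant = sum(category == "target_relevant"),
              noise_administrative = sum(category == "noise_administrative"),
              proxy_downstream = sum(category == "proxy_downstream"))
  structure(list(counts = counts, n = length(category),
                 by_variable = data.frame(variable = ranking$variable,
                                          category = category,
                                          stringsAsFactors = FALSE)),
            class = "audit_report")
}

## Trace an encoded design column (e.g. "site=SITE2") back to its catalog
## variable; plain names pass through.
source_variable <- function(cols, catalog) {
  base <- sub("=.*$", "", cols)
  ifelse(base %in% catalog$name, base, NA_character_)
}

#' @export
print.audit_report <- function(x, ...) {
  if (is.data.frame(x)) {
    cat("Semantic audit (per method):\n")
    print.data.frame(x)
  } else {
    cat("Semantic audit of", x$n, "selected features:\n")
    for (nm in names(x$counts)) cat(sprintf("  %-22s %d\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}

#' @export
print.feature_ranking <- function(x, n = 10, ...) {
  cat(sprintf("Feature ranking (%s, top %d of %d kept)\n",
              attr(x, "selection_method"), nrow(x), attr(x, "k")))
  print.data.frame(utils::head(x[, intersect(c("variable", "score", "classification"),
                                             names(x)), drop = FALSE], n))
  invisible(x)
}
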