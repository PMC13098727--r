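#' Critic check on score/class band consistency
#' @keywords internal
critic_check_decision_fields <- function(score, classification) {
  if (is.na(score) || score < 0 || score > 1) {
    return(list(verdict = "reject",
                reason = sprintf("relevance_score %s outside [0,1]", score)))
  }
  band_ok <- switch(classification,
                    Direct = score >= 0.7,
                    Unrelated = score < 0.3,
                    Indirect = score >= 0.3 && score < 0.7,
                    FALSE)
  if (!band_ok) {
    return(list(verdict = "flag",
                reason = sprintf("classification '%s' inconsistent with score %.2f",
                                 classification, score)))
  }
  list(verdict = "pass", reason = "schema valid, score in band")
}

#' Critic check of a relevance decision
#'
#' Validates schema and score range (reject on violation) and semantic
#' consistency between classification and score using declared bands:
#' `Direct` requires a score of at least 0.7, `Unrelated` a score below
#' 0.3, `Indirect` the band between (flag on inconsistency, which triggers
#' the agent's single requery). Rejected decisions never propagate
#' downstream.
#'
#' @param decision A `relevance_decision`.
#' @return A `critic_report` with `check`, `target`, `verdict`
#'   (`pass`/`flag`/`reject`), and `reason`.
#' @export
critic_check_decision <- function(decision) {
  stopifnot(inherits(decision, "relevance_decision"))
  v <- critic_check_decision_fields(decision$relevance_score,
                                    decision$classification)
  structure(list(check = "decision_schema_and_bands",
                 target = decision$variable,
                 verdict = v$verdict, reason = v$reason),
            class = "critic_report")
}

#' Critic check of a scenario's actionability
#'
#' Rejects any scenario perturbing a variable flagged `modifiable = FALSE`
#' in the catalog — administrative artifacts and downstream proxies such as
#' prescription-medication checklists are not upstream modifiable
#' determinants, so perturbing them is semantically inconsistent with the
#' twin's intervention scope. The reason names exactly the offending
#' variables.
#'
#' @param scenario A `scenario_spec`.
#' @param catalog A [variable_catalog()].
#' @return A `critic_report`.
#' @export
critic_check_scenario <- function(scenario, catalog) {
  stopifnot(inherits(scenario, "scenario_spec"))
  vars <- vapply(scenario$perturbations, function(p) p$variable, character(1))
  missing <- setdiff(vars, catalog$name)
  if (length(missing)) {
    stop("scenario names variable(s) absent from catalog: ",
         paste(missing, collapse = ", "))
  }
  offending <- vars[!catalog$modifiable[match(vars, catalog$name)]]
  if (length(offending)) {
    structure(list(check = "scenario_actionability", target = scenario$name,
                   verdict = "reject",
                   reason = paste0("non-modifiable variable(s): ",
                                   paste(offending, collapse = ", "))),
              class = "critic_report")
  } else {
    structure(list(check = "scenario_actionability", target = scenario$name,
                   verdict = "pass",
                   reason = "all perturbed variables are modifiable"),
              class = "critic_report")
  }
}

#' @export
print.critic_report <- function(x, ...) {
  cat(sprintf("Critic [%s] %s: %s (%s)\n", x$check, x$target, x$verdict,
              x$reason))
  invisible(x)
}

#' Deterministic hub-and-spoke pipeline run
#'
#' Executes the full twin-construction pipeline in dependency order —
#' cohort generation, ontology index, agent feature selection, predictor
#' training, state construction, transition/outcome fitting, and scenario
#' simulation — as a deterministic controller with critic hooks at the two
#' validation points (decision bands, scenario actionability). Every stage
#' writes its artifact under `out_dir` and is content-digested into the run
#' manifest; reruns from the same config reproduce the digests exactly.
#'
#' @param config Named list (or path to a JSON file): must carry `seed`;
#'   optional entries `cohort` (arguments to [cohort_spec()]), `ontology`
#'   (fixture paths; default: the packaged synthetic diabetes ontology),
#'   `select` (`top_k`, `batch_size`), `twin` (arguments to [build_twin()]),
#'   `scenarios` (paths to scenario JSON files), and `stages` (character
#'   vector enabling a subset).
#' @param out_dir Output directory for artifacts and the manifest.
#' @return A `run_manifest` (also written to `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config, out_dir = tempfile("twinforge_run_")) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (is.null(config$seed)) stop("config must set an explicit seed")
  seed <- as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_stages <- c("cohort", "index", "select", "train", "states",
                  "transition_outcome", "scenarios")
  stages <- if (is.null(config$stages)) all_stages else
    intersect(all_stages, config$stages)
  manifest <- list(config = config, tool_version = as.character(
    utils::packageVersion("twinforge")), stages = list(), critics = list())
  add_stage <- function(name, artifact_path, t0) {
    manifest$stages[[name]] <<- list(
      name = name, artifact = basename(artifact_path),
      digest = file_digest(artifact_path),
      seconds = round(as.numeric(Sys.time()) - t0, 3))
  }
  panel <- NULL; twin <- NULL; ranking <- NULL; index <- NULL
  if ("cohort" %in% stages) {
    t0 <- as.numeric(Sys.time())
    args <- config$cohort
    if (is.null(args)) args <- list()
    if (is.null(args$seed)) args$seed <- seed
    spec <- do.call(cohort_spec, args)
    panel <- generate_cohort(spec)
    path <- file.path(out_dir, "panel.csv")
    write_panel(panel, path)
    add_stage("cohort", path, t0)
  }
  if ("index" %in% stages) {
    t0 <- as.numeric(Sys.time())
    paths <- config$ontology
    if (is.null(paths)) {
      paths <- system.file("extdata", "synthetic_diabetes_ontology.json",
                           package = "twinforge")
    }
    onto <- load_ontology(paths)
    index <- build_index(onto, hash_embedder())
    path <- file.path(out_dir, "index.json")
    jsonlite::write_json(list(embedder_id = index$embedder_id,
                              iris = rownames(index$vectors),
                              vectors = unname(apply(index$vectors, 1,
                                                     function(v) v,
                                                     simplify = FALSE))),
                         path, auto_unbox = TRUE, digits = NA)
    add_stage("index", path, t0)
  }
  if ("select" %in% stages && !is.null(panel)) {
    t0 <- as.numeric(Sys.time())
    sel <- config$select
    backend <- stub_backend_domain(panel$catalog)
    ranking <- select_features(panel$catalog, index, backend,
                               top_k = if (is.null(sel$top_k)) 200 else sel$top_k,
                               batch_size = if (is.null(sel$batch_size)) 40 else sel$batch_size,
                               log_path = file.path(out_dir, "agent_log.jsonl"))
    ## critic hook: rejected decisions never enter the ranking artifact
    reports <- lapply(attr(ranking, "decisions"), function(d) {
      if (d$excluded) NULL else critic_check_decision(d)
    })
    reports <- Filter(Negate(is.null), reports)
    rejected <- vapply(reports, function(r) r$verdict == "reject", logical(1))
    manifest$critics$decisions <- list(checked = length(reports),
                                       rejected = sum(rejected))
    if (any(rejected)) {
      bad <- vapply(reports[rejected], function(r) r$target, character(1))
      ranking <- ranking[!ranking$variable %in% bad, , drop = FALSE]
    }
    path <- file.path(out_dir, "ranking.json")
    jsonlite::write_json(data.frame(variable = ranking$variable,
                                    score = ranking$score,
                                    classification = ranking$classification,
                                    reasoning = ranking$reasoning,
                                    requery_count = ranking$requery_count,
                                    stringsAsFactors = FALSE),
                         path, auto_unbox = TRUE, digits = NA)
    add_stage("select", path, t0)
  }
  if (any(c("train", "states", "transition_outcome", "scenarios") %in% stages) &&
      !is.null(panel)) {
    t0 <- as.numeric(Sys.time())
    targs <- config$twin
    if (is.null(targs)) targs <- list()
    targs$panel <- panel
    if (!is.null(ranking)) {
      targs$features <- source_variable(ranking$variable, panel$catalog)
    }
    if (is.null(targs$seed)) targs$seed <- seed
    twin <- do.call(build_twin, targs)
    if ("train" %in% stages) {
      path <- file.path(out_dir, "metrics.json")
      jsonlite::write_json(twin$predictor$metrics, path, auto_unbox = TRUE,
                           digits = NA)
      add_stage("train", path, t0)
    }
    if ("states" %in% stages) {
      t1 <- as.numeric(Sys.time())
      path <- file.path(out_dir, "states.json")
      jsonlite::write_json(list(K = twin$states$K,
                                centroids = twin$states$centroids,
                                labels = twin$states$labels,
                                sizes = twin$states$sizes),
                           path, auto_unbox = TRUE, digits = NA)
      add_stage("states", path, t1)
    }
    if ("transition_outcome" %in% stages) {
      t1 <- as.numeric(Sys.time())
      path <- file.path(out_dir, "transition_outcome.json")
      jsonlite::write_json(list(
        transition = list(model = twin$transition$model,
                          accuracy = twin$transition$accuracy,
                          macro_f1 = twin$transition$macro_f1,
                          avg_log_likelihood = twin$transition$avg_log_likelihood,
                          brier = twin$transition$brier,
                          ece = twin$transition$ece),
        outcome = list(model = twin$outcome$model, auc = twin$outcome$auc,
                       pr_auc = twin$outcome$pr_auc,
                       brier = twin$outcome$brier)),
        path, auto_unbox = TRUE, digits = NA)
      add_stage("transition_outcome", path, t1)
    }
  }
  if ("scenarios" %in% stages && !is.null(twin)) {
    t0 <- as.numeric(Sys.time())
    paths <- config$scenarios
    if (is.null(paths)) {
      paths <- system.file("extdata",
                           c("scenario_weight10.json", "scenario_lifestyle.json"),
                           package = "twinforge")
    }
    results <- list()
    for (p in paths) {
      sc <- read_scenario(p)
      critic <- critic_check_scenario(sc, twin$panel$catalog)
      manifest$critics$scenarios[[sc$name]] <- critic$verdict
      if (critic$verdict == "reject") next
      r <- simulate_scenario(twin, sc)
      results[[sc$name]] <- scenario_result_summary(r)
    }
    path <- file.path(out_dir, "scenario_results.json")
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA)
    add_stage("scenarios", path, t0)
  }
  manifest <- structure(manifest, class = "run_manifest")
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  attr(manifest, "out_dir") <- out_dir
  manifest
}

scenario_result_summary <- function(r) {
  list(scenario = r$scenario, n = r$n,
       baseline = r$baseline, perturbed = r$perturbed,
       n_state_changed = r$n_state_changed,
       n_high_to_low = r$n_high_to_low,
       n_risk_reduced = r$n_risk_reduced)
}

#' Write / read / verify a run manifest
#'
#' The manifest records the config snapshot, tool version, per-stage
#' artifact digests (md5 content hashes) and timings, and critic reports.
#' `verify_manifest()` recomputes every artifact digest against the files
#' on disk and reports mismatches (detecting post-run modification).
#'
#' @param manifest A `run_manifest`.
#' @param path JSON path.
#' @return `write_manifest` invisibly returns `path`; `read_manifest`
#'   returns the manifest; `verify_manifest` returns a data frame with one
#'   row per stage and a logical `ok` column.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "run_manifest")
}

#' @rdname write_manifest
#' @param dir Directory holding the run artifacts (defaults to the
#'   manifest's directory).
#' @export
verify_manifest <- function(path, dir = dirname(path)) {
  m <- read_manifest(path)
  st <- m$stages
  rows <- lapply(names(st), function(nm) {
    f <- file.path(dir, st[[nm]]$artifact)
    ok <- file.exists(f) && identical(unname(file_digest(f)), st[[nm]]$digest)
    data.frame(stage = nm, artifact = st[[nm]]$artifact,
               expected = st[[nm]]$digest,
               actual = if (file.exists(f)) unname(file_digest(f)) else NA_character_,
               ok = ok, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stage = character(), artifact = character(),
               expected = character(), actual = character(), ok = logical())
  out
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Run manifest (twinforge", x$tool_version, ")\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-20s %s  %ss\n", nm, s$digest, s$seconds))
  }
  invisible(x)
}
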