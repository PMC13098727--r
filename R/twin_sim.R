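#' Fit discrete risk states by exact one-dimensional k-means
#'
#' Clusters the baseline predicted-risk scores into `K` strata. Because the
#' scores are one-dimensional, the globally optimal k-means solution is the
#' best contiguous partition of the sorted values, which is computed exactly
#' by dynamic programming over within-cluster sums of squares — no random
#' initialization, so the fit is deterministic by construction (the `seed`
#' argument is recorded for interface compatibility). Centroids are sorted
#' ascending and labeled low to high (`low`, `medium`, `high` for K = 3);
#' they are frozen at baseline and reused for every later assignment.
#'
#' @param risk Numeric vector of probabilities in `[0, 1]` with at least `K`
#'   distinct values.
#' @param K Number of states (>= 2); default 3, aligning with standard
#'   clinical low/medium/high stratification.
#' @param seed Recorded in the model; the fit itself is deterministic.
#' @return A `risk_state_model` with sorted `centroids`, `labels`, per-state
#'   `sizes`, cluster `assignment` of the training scores, and `sse`.
#' @export
fit_states <- function(risk, K = 3, seed = 1) {
  if (K < 2) stop("K must be at least 2")
  if (any(risk < 0 | risk > 1)) stop("risks must lie in [0, 1]")
  if (length(unique(risk)) < K) stop("fewer distinct risk values than K")
  ord <- order(risk)
  x <- risk[ord]
  n <- length(x)
  cum <- c(0, cumsum(x)); cum2 <- c(0, cumsum(x^2))
  sse_seg <- function(j, i) {
    ## within-SSE of x[j..i] (vectorized over j)
    s <- cum[i + 1] - cum[j]; s2 <- cum2[i + 1] - cum2[j]
    s2 - s^2 / (i - j + 1)
  }
  D <- matrix(Inf, n, K)
  B <- matrix(NA_integer_, n, K)
  D[, 1] <- sse_seg(1, seq_len(n))
  B[, 1] <- 1L
  for (k in 2:K) {
    for (i in k:n) {
      j <- k:i
      val <- D[j - 1, k - 1] + sse_seg(j, i)
      best <- which.min(val)                 # smallest j on ties
      D[i, k] <- val[best]
      B[i, k] <- j[best]
    }
  }
  bounds <- integer(K + 1); bounds[K + 1] <- n
  i <- n
  for (k in K:1) {
    j <- B[i, k]
    bounds[k] <- j - 1L
    i <- j - 1L
  }
  cluster_sorted <- rep(seq_len(K), diff(bounds))
  centroids <- vapply(seq_len(K),
                      function(k) mean(x[cluster_sorted == k]), numeric(1))
  assignment <- integer(n)
  assignment[ord] <- cluster_sorted
  labels <- if (K == 3) c("low", "medium", "high") else
    paste0("state", seq_len(K))
  structure(list(K = K, centroids = centroids, labels = labels,
                 sizes = as.integer(table(factor(assignment, levels = seq_len(K)))),
                 assignment = assignment, sse = D[n, K], fit_seed = seed),
            class = "risk_state_model")
}

#' @export
print.risk_state_model <- function(x, ...) {
  cat(sprintf("Risk-state model (K = %d, exact 1-D k-means)\n", x$K))
  for (k in seq_len(x$K)) {
    cat(sprintf("  %-8s centroid %.4f  n = %d\n", x$labels[k],
                x$centroids[k], x$sizes[k]))
  }
  invisible(x)
}

#' Assign risks to states by nearest frozen centroid
#'
#' Wave-3 (or any new) risks are assigned with the wave-2 centroids
#' unchanged; a risk exactly midway between two centroids goes to the
#' lower-risk state (conservative, deterministic tie-break).
#'
#' @param risk Probability vector in `[0, 1]`.
#' @param model A `risk_state_model`.
#' @return Integer state indices (1 = lowest risk) with the model's labels
#'   as a `labels` attribute.
#' @export
assign_states <- function(risk, model) {
  stopifnot(inherits(model, "risk_state_model"))
  if (any(risk < 0 | risk > 1)) stop("risks must lie in [0, 1]")
  d <- abs(outer(risk, model$centroids, "-"))
  ## ties.method = "first" sends exact midpoints to the lower-risk state
  s <- max.col(-d, ties.method = "first")
  attr(s, "labels") <- model$labels
  s
}

#' Size-matched high-risk union across K
#'
#' For K > 3 state models, the high-risk population is defined as the union
#' of highest-centroid clusters whose combined membership first reaches the
#' K = 3 high-risk group size, preserving semantic comparability across K.
#' The union always contains at least the top cluster.
#'
#' @param model A `risk_state_model`.
#' @param reference_high_size Membership count of the reference (K = 3)
#'   high-risk group.
#' @return Integer vector of cluster indices, highest centroid first.
#' @export
high_risk_union <- function(model, reference_high_size) {
  stopifnot(inherits(model, "risk_state_model"))
  if (reference_high_size > sum(model$sizes)) {
    stop("reference size exceeds the population")
  }
  ord <- order(model$centroids, decreasing = TRUE)
  cum <- cumsum(model$sizes[ord])
  take <- max(1L, which(cum >= reference_high_size)[1])
  if (is.na(take)) take <- length(ord)
  ord[seq_len(take)]
}

one_hot_states <- function(s, K, prefix = "s") {
  m <- outer(s, seq_len(K), "==") * 1
  colnames(m) <- paste0(prefix, seq_len(K))
  m
}

#' Fit the wave-2 to wave-3 state-transition model
#'
#' Multiclass classifier for P(next state | baseline state, baseline
#' features), trained with stratified k-fold cross-validation. Inputs are
#' the baseline design matrix plus the one-hot baseline state. Reports
#' out-of-fold accuracy (with per-fold SD), macro-F1, average
#' log-likelihood of the realized next state, and multiclass Brier/ECE.
#' Out-of-fold soft predictions are retained for cross-fitted downstream
#' use.
#'
#' @param x_w2 Baseline design matrix.
#' @param s_w2,s_w3 Integer state vectors from [assign_states()].
#' @param K Number of states.
#' @param model `"gradient_boosted_trees"`, `"random_forest"`, or
#'   `"logistic"` (multinomial).
#' @param folds,seed Cross-validation controls.
#' @param nrounds Boosting rounds for the boosted-tree model.
#' @return A `transition_model` with the refit classifier, `oof_soft`
#'   probability matrix (cross-fitted), and metrics.
#' @export
fit_transition <- function(x_w2, s_w2, s_w3, K = max(c(s_w2, s_w3)),
                           model = "gradient_boosted_trees", folds = 5,
                           seed = 1, nrounds = 150) {
  stopifnot(nrow(x_w2) == length(s_w2), length(s_w2) == length(s_w3))
  X <- cbind(x_w2, one_hot_states(s_w2, K, "s_w2_"))
  present <- sort(unique(s_w3))
  if (length(present) < K) {
    warning("state(s) absent from wave-3 labels: ",
            paste(setdiff(seq_len(K), present), collapse = ", "))
  }
  fold <- stratified_folds(s_w3, folds, seed)
  p_oof <- matrix(NA_real_, nrow(X), length(present),
                  dimnames = list(NULL, as.character(present)))
  acc_f <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- which(fold != f); ev <- which(fold == f)
    fit <- fit_classifier(model, X[tr, , drop = FALSE], s_w3[tr],
                          seed = seed + f, multiclass = TRUE,
                          nrounds = nrounds)
    p <- predict_classifier_multi(fit, X[ev, , drop = FALSE])
    p_oof[ev, colnames(p)] <- p
    acc_f[f] <- accuracy_score(s_w3[ev],
                               as.integer(colnames(p)[max.col(p, ties.method = "first")]))
  }
  p_oof[is.na(p_oof)] <- 0
  pred <- as.integer(colnames(p_oof)[max.col(p_oof, ties.method = "first")])
  eps <- 1e-12
  idx <- cbind(seq_along(s_w3), match(as.character(s_w3), colnames(p_oof)))
  avg_ll <- mean(log(pmax(p_oof[idx], eps)))
  cal <- calibration_metrics(s_w3, p_oof)
  final <- fit_classifier(model, X, s_w3, seed = seed, multiclass = TRUE,
                          nrounds = nrounds)
  structure(list(fit = final, model = model, K = K, classes = present,
                 feature_names = colnames(X),
                 oof_soft = p_oof, cross_fitted = TRUE,
                 accuracy = mean(acc_f), accuracy_sd = sd(acc_f),
                 macro_f1 = macro_f1(s_w3, pred),
                 avg_log_likelihood = avg_ll,
                 brier = cal$brier, ece = cal$ece,
                 fold = fold, seed = seed),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("State-transition model (%s)\n", x$model))
  cat(sprintf("  accuracy %.3f (SD %.3f)  macro-F1 %.3f\n",
              x$accuracy, x$accuracy_sd, x$macro_f1))
  cat(sprintf("  avg log-likelihood %.4f  Brier %.4f  ECE %.4f\n",
              x$avg_log_likelihood, x$brier, x$ece))
  invisible(x)
}

#' Predict next-state probabilities
#'
#' @param object A `transition_model`.
#' @param x_w2 Baseline design matrix.
#' @param s_w2 Baseline state vector.
#' @param ... Unused.
#' @return Probability matrix, one column per (observed) state, rows
#'   summing to 1.
#' @export
predict.transition_model <- function(object, x_w2, s_w2, ...) {
  X <- cbind(x_w2, one_hot_states(s_w2, object$K, "s_w2_"))
  stopifnot(identical(colnames(X), object$feature_names))
  predict_classifier_multi(object$fit, X)
}

#' Fit the wave-3 outcome model on cross-fitted soft states
#'
#' Binary classifier for P(outcome | baseline features, baseline state,
#' predicted next-state probabilities). The soft next-state inputs must be
#' out-of-fold predictions from [fit_transition()] (cross-fitting); passing
#' a matrix not flagged as cross-fitted trips the leakage detector.
#'
#' @param x_w2 Baseline design matrix.
#' @param s_w2 Baseline state vector.
#' @param p_s_w3_soft Out-of-fold next-state probability matrix.
#' @param y_w3 Binary outcome.
#' @param K Number of states.
#' @param model Classifier name as in [train_predictors()].
#' @param folds,seed Cross-validation controls.
#' @param oversample Apply SMOTE in training folds (default off).
#' @param cross_fitted Assertion that the soft inputs are out-of-fold.
#' @return An `outcome_model` with AUC/PR-AUC/Brier metrics.
#' @export
fit_outcome <- function(x_w2, s_w2, p_s_w3_soft, y_w3,
                        K = max(s_w2), model = "gradient_boosted_trees",
                        folds = 5, seed = 1, oversample = FALSE,
                        cross_fitted = isTRUE(attr(p_s_w3_soft, "cross_fitted"))) {
  if (!cross_fitted) {
    stop("leakage detector: soft next-state inputs must be out-of-fold ",
         "(cross-fitted) transition predictions")
  }
  soft <- as.matrix(p_s_w3_soft)
  colnames(soft) <- paste0("p_s_w3_", colnames(soft))
  X <- cbind(x_w2, one_hot_states(s_w2, K, "s_w2_"), soft)
  b <- train_predictors(X, y_w3, models = model, folds = folds,
                        oversample = oversample, seed = seed)
  structure(list(bundle = b, model = model, K = K,
                 feature_names = colnames(X),
                 auc = b$metrics$auc[1], pr_auc = b$metrics$pr_auc[1],
                 brier = b$metrics$brier[1], seed = seed),
            class = "outcome_model")
}

#' @export
print.outcome_model <- function(x, ...) {
  cat(sprintf("Outcome model (%s): AUC %.3f  PR-AUC %.3f  Brier %.4f\n",
              x$model, x$auc, x$pr_auc, x$brier))
  invisible(x)
}

#' Predict outcome risk
#'
#' @param object An `outcome_model`.
#' @param x_w2 Baseline design matrix.
#' @param s_w2 Baseline states.
#' @param p_s_w3_soft Next-state probability matrix (deployment-time soft
#'   states from the refit transition model).
#' @param ... Unused.
#' @return Probability vector.
#' @export
predict.outcome_model <- function(object, x_w2, s_w2, p_s_w3_soft, ...) {
  soft <- as.matrix(p_s_w3_soft)
  colnames(soft) <- paste0("p_s_w3_", colnames(soft))
  X <- cbind(x_w2, one_hot_states(s_w2, object$K, "s_w2_"), soft)
  stopifnot(identical(colnames(X), object$feature_names))
  predict_classifier(object$bundle$fits[[object$model]], X)
}

## ---- scenarios ---------------------------------------------------------

#' Declare a what-if scenario
#'
#' @param name Scenario name.
#' @param perturbations List of perturbations, each
#'   `list(variable =, kind = "multiplicative"|"additive"|"ordinal_shift"|
#'   "categorical_set", value =)`. Multiplicative values are relative changes
#'   (`-0.10` = a 10% decrease).
#' @param propagate List of derived-feature rules
#'   `list(from =, to =, rule = "same_relative")`: the relative change
#'   applied to `from` is propagated to `to` (e.g. weight to BMI at fixed
#'   height).
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(name, perturbations, propagate = list()) {
  for (p in perturbations) {
    stopifnot(!is.null(p$variable), !is.null(p$kind), !is.null(p$value))
    match.arg(p$kind, c("multiplicative", "additive", "ordinal_shift",
                        "categorical_set"))
  }
  structure(list(name = name, perturbations = perturbations,
                 propagate = propagate), class = "scenario_spec")
}

#' Read / write scenario specifications as JSON
#'
#' @param path JSON file path.
#' @return A `scenario_spec`.
#' @export
read_scenario <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  scenario_spec(doc$name, doc$perturbations, if (is.null(doc$propagate))
    list() else doc$propagate)
}

#' @rdname read_scenario
#' @param scenario A `scenario_spec`.
#' @export
write_scenario <- function(scenario, path) {
  jsonlite::write_json(unclass(scenario), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Apply a scenario's perturbations to the baseline wave
#'
#' Perturbations touch wave-2 values only. Every perturbed variable must be
#' flagged `modifiable` in the catalog (perturbing a non-modifiable
#' variable, e.g. a medication checklist, is rejected — the critic rule).
#' Ordinal shifts are rounded and clamped to the scale bounds; additive and
#' multiplicative changes respect declared scale bounds (e.g. scores floor
#' at their minimum). Relative changes propagate along the declared
#' derived-feature rules. Untouched variables are returned bit-identical.
#'
#' @param panel A `cohort_panel`.
#' @param scenario A `scenario_spec`.
#' @return The panel with perturbed wave-2 values.
#' @export
apply_scenario <- function(panel, scenario) {
  stopifnot(inherits(panel, "cohort_panel"), inherits(scenario, "scenario_spec"))
  catalog <- panel$catalog
  w2 <- panel$w2
  rel_change <- list()
  for (p in scenario$perturbations) {
    v <- p$variable
    row <- catalog_row(catalog, v)
    if (!row$modifiable) {
      stop("scenario perturbs non-modifiable variable '", v,
           "' (rejected: not an upstream modifiable determinant)")
    }
    if (!v %in% names(w2)) stop("panel lacks variable '", v, "'")
    x <- w2[[v]]
    if (p$kind == "multiplicative") {
      x <- x * (1 + p$value)
      rel_change[[v]] <- p$value
    } else if (p$kind == "additive") {
      x <- x + p$value
    } else if (p$kind == "ordinal_shift") {
      x <- round(x) + p$value
    } else if (p$kind == "categorical_set") {
      x <- rep(p$value, length(x))
    }
    x <- clamp_to_scale(x, row)
    w2[[v]] <- x
  }
  for (rule in scenario$propagate) {
    if (!is.null(rel_change[[rule$from]])) {
      row <- catalog_row(catalog, rule$to)
      if (!row$modifiable) {
        stop("propagation targets non-modifiable variable '", rule$to, "'")
      }
      x <- w2[[rule$to]] * (1 + rel_change[[rule$from]])
      w2[[rule$to]] <- clamp_to_scale(x, row)
    }
  }
  panel$w2 <- w2
  panel
}

clamp_to_scale <- function(x, row) {
  if (row$dtype == "ordinal") x <- round(x)
  if (!is.na(row$scale_min)) x <- pmax(x, row$scale_min)
  if (!is.na(row$scale_max)) x <- pmin(x, row$scale_max)
  x
}

#' Run a what-if scenario through the fitted twin
#'
#' Runs the baseline and the perturbed panel through the identical
#' deterministic pipeline: preprocess with the frozen plan, rebuild the
#' design matrix, predict next-state probabilities with the transition
#' model (baseline states held fixed as conditioning inputs), predict
#' outcome risk with the outcome model, take hard next states by maximum
#' probability, and count cases at the decision threshold. Reports
#' population state distributions, predicted case counts, mean risk,
#' per-participant risk deltas, state-change and high-to-low counts, and
#' the number of participants with strictly reduced risk. A zero-magnitude
#' (placebo) scenario yields exactly zero change in every quantity.
#'
#' @param twin A `digital_twin` from [build_twin()].
#' @param scenario A `scenario_spec`.
#' @param case_threshold Risk threshold for the predicted case count.
#' @return A `scenario_result`.
#' @export
simulate_scenario <- function(twin, scenario,
                              case_threshold = twin$case_threshold) {
  stopifnot(inherits(twin, "digital_twin"))
  critic <- critic_check_scenario(scenario, twin$panel$catalog)
  if (critic$verdict == "reject") {
    stop("critic rejected scenario '", scenario$name, "': ", critic$reason)
  }
  centroid_hash <- object_digest(twin$states$centroids)
  run_arm <- function(panel_raw) {
    w2p <- apply_preprocess(twin$plan, panel_raw$w2)
    X <- build_design(w2p, twin$panel$catalog, encoder = twin$encoder)$X
    soft <- predict(twin$transition, X, twin$s_w2)
    risk <- predict(twin$outcome, X, twin$s_w2, soft)
    hard <- as.integer(colnames(soft)[max.col(soft, ties.method = "first")])
    list(soft = soft, risk = risk, hard = hard)
  }
  base <- run_arm(twin$panel_raw)
  pert <- run_arm(apply_scenario(twin$panel_raw, scenario))
  stopifnot(identical(object_digest(twin$states$centroids), centroid_hash))
  K <- twin$states$K
  frac <- function(hard) as.numeric(table(factor(hard, levels = seq_len(K))) /
                                      length(hard))
  delta <- pert$risk - base$risk
  res <- structure(list(
    scenario = scenario$name,
    n = length(base$risk),
    state_labels = twin$states$labels,
    baseline = list(state_fractions = frac(base$hard),
                    predicted_cases = sum(base$risk >= case_threshold),
                    mean_risk = mean(base$risk)),
    perturbed = list(state_fractions = frac(pert$hard),
                     predicted_cases = sum(pert$risk >= case_threshold),
                     mean_risk = mean(pert$risk)),
    risk_delta = delta,
    n_state_changed = sum(base$hard != pert$hard),
    n_high_to_low = sum(base$hard == K & pert$hard == 1),
    n_risk_reduced = sum(delta < 0),
    case_threshold = case_threshold),
    class = "scenario_result")
  attr(res, "log") <- list(scenario = scenario$name,
                           critic = critic$verdict,
                           centroid_digest = centroid_hash,
                           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"))
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario '%s' (n = %d)\n", x$scenario, x$n))
  cat(sprintf("  predicted cases: %d -> %d (%+d)\n",
              x$baseline$predicted_cases, x$perturbed$predicted_cases,
              x$perturbed$predicted_cases - x$baseline$predicted_cases))
  cat(sprintf("  mean risk:       %.4f -> %.4f\n",
              x$baseline$mean_risk, x$perturbed$mean_risk))
  cat(sprintf("  any state change: %d (%.1f%%); high -> low: %d; risk reduced: %d (%.1f%%)\n",
              x$n_state_changed, 100 * x$n_state_changed / x$n,
              x$n_high_to_low, x$n_risk_reduced, 100 * x$n_risk_reduced / x$n))
  fr <- rbind(baseline = x$baseline$state_fractions,
              perturbed = x$perturbed$state_fractions)
  colnames(fr) <- x$state_labels
  print(round(fr, 4))
  invisible(x)
}

#' Monotonicity sweep over perturbation magnitudes
#'
#' Simulates a multiplicative reduction of the given continuous modifiable
#' variable at each magnitude and reports the mean predicted risk sequence
#' and whether it is monotone non-increasing.
#'
#' @param twin A `digital_twin`.
#' @param variable Perturbed variable (continuous, modifiable).
#' @param magnitudes Relative reductions, e.g. `c(0.05, 0.10, 0.15)`.
#' @param propagate Derived-feature rules applied at every magnitude.
#' @return List with the per-magnitude data frame `sweep` (magnitude,
#'   mean_risk, predicted_cases) and logical `monotone_nonincreasing`.
#' @export
monotonicity_sweep <- function(twin, variable = "weight_lbs",
                               magnitudes = c(0.05, 0.10, 0.15),
                               propagate = list(list(from = variable,
                                                     to = "bmi",
                                                     rule = "same_relative"))) {
  if (!length(magnitudes)) stop("magnitudes must be non-empty")
  rows <- lapply(magnitudes, function(m) {
    sc <- scenario_spec(sprintf("%s_minus_%.0f_percent", variable, 100 * m),
                        list(list(variable = variable, kind = "multiplicative",
                                  value = -m)),
                        propagate = propagate)
    r <- simulate_scenario(twin, sc)
    data.frame(magnitude = m, mean_risk = r$perturbed$mean_risk,
               predicted_cases = r$perturbed$predicted_cases)
  })
  sweep <- do.call(rbind, rows)
  list(sweep = sweep,
       monotone_nonincreasing = !is.unsorted(-sweep$mean_risk, strictly = FALSE))
}

#' Cross-K stability of the high-risk state
#'
#' Fits state models for each K in `K_range` on the baseline risks, derives
#' the size-matched high-risk union for each (reference: the K = 3 high-risk
#' group), and reports high-risk membership sets, sizes, and the pairwise
#' Jaccard overlap matrix. Given a fitted twin, transition models are refit
#' per K and accuracy deltas against K = 3 are included.
#'
#' @param x A `digital_twin` or a numeric baseline risk vector.
#' @param K_range Integer vector of K values (each >= 2); must include 3.
#' @param seed Seed recorded in the state fits / used for transition refits.
#' @param ids Participant identifiers (defaults to positions).
#' @return List with `high_sets`, `sizes`, `jaccard` matrix, and (twin only)
#'   `transition_accuracy`.
#' @export
stability_analysis <- function(x, K_range = 3:5, seed = 1, ids = NULL) {
  if (any(K_range < 2)) stop("all K in K_range must be >= 2")
  if (!3 %in% K_range) stop("K_range must include the K = 3 reference")
  twin <- NULL
  if (inherits(x, "digital_twin")) { twin <- x; risk <- twin$risk_w2 }
  else risk <- x
  if (is.null(ids)) ids <- seq_along(risk)
  models <- lapply(K_range, function(K) fit_states(risk, K, seed))
  names(models) <- as.character(K_range)
  ref_model <- models[["3"]]
  ref_high <- which(ref_model$assignment == ref_model$K)
  ref_size <- length(ref_high)
  high_sets <- lapply(models, function(m) {
    ids[m$assignment %in% high_risk_union(m, ref_size)]
  })
  J <- outer(seq_along(K_range), seq_along(K_range),
             Vectorize(function(i, j) jaccard_overlap(high_sets[[i]],
                                                      high_sets[[j]])))
  dimnames(J) <- list(paste0("K", K_range), paste0("K", K_range))
  out <- list(K_range = K_range,
              high_sets = high_sets,
              sizes = vapply(high_sets, length, integer(1)),
              reference_high_size = ref_size,
              jaccard = J)
  if (!is.null(twin)) {
    acc <- vapply(models, function(m) {
      s2 <- assign_states(twin$risk_w2, m)
      s3 <- assign_states(twin$risk_w3, m)
      tm <- fit_transition(twin$X_w2, s2, s3, K = m$K,
                           model = twin$transition$model, folds = 5,
                           seed = seed, nrounds = 60)
      tm$accuracy
    }, numeric(1))
    out$transition_accuracy <- acc
    out$transition_accuracy_delta <- acc - acc[["3"]]
  }
  out
}

## ---- the twin itself ---------------------------------------------------

#' Build a digital twin from a two-wave cohort panel
#'
#' The end-to-end fit: (1) clean/impute the panel and freeze the
#' preprocessing plan on wave 2; (2) train the cross-validated risk
#' predictor menu on wave-2 features against the wave-3 outcome and keep
#' the best-AUC model; (3) score wave-2 risk out-of-fold and wave-3 risk by
#' applying the same wave-2-trained predictor to wave-3 features; (4) fit
#' K risk states on the wave-2 risks (centroids frozen thereafter) and
#' assign both waves; (5) fit the state-transition model and, on its
#' cross-fitted soft outputs, the outcome model. The returned object powers
#' `predict()`, `simulate()` (scenario engine), [monotonicity_sweep()] and
#' [stability_analysis()].
#'
#' @param panel A `cohort_panel` with observed `outcome_w3`.
#' @param features Variables to use (default: all catalog variables).
#' @param models Risk-predictor menu for [train_predictors()].
#' @param K Number of risk states.
#' @param folds,seed Cross-validation controls.
#' @param oversample SMOTE inside predictor training folds.
#' @param transition_model,outcome_model Classifier names for the two
#'   simulation stages.
#' @param case_threshold Risk threshold defining a predicted case.
#' @param nrounds Boosting rounds for boosted-tree fits.
#' @return A `digital_twin` object.
#' @export
build_twin <- function(panel, features = NULL,
                       models = c("logistic", "gradient_boosted_trees"),
                       K = 3, folds = 5, seed = 42, oversample = TRUE,
                       transition_model = "gradient_boosted_trees",
                       outcome_model = "gradient_boosted_trees",
                       case_threshold = 0.5, nrounds = 150) {
  stopifnot(inherits(panel, "cohort_panel"))
  if (anyNA(panel$outcome_w3)) stop("panel lacks a complete wave-3 outcome")
  pre <- clean_and_impute(panel)
  d2 <- build_design(pre$panel$w2, pre$panel$catalog, features)
  d3 <- build_design(pre$panel$w3, pre$panel$catalog, encoder = d2$encoder)
  y <- as.numeric(panel$outcome_w3)
  bundle <- train_predictors(d2$X, y, models = models, folds = folds,
                             oversample = oversample, seed = seed,
                             domains = d2$domains)
  risk_w2 <- bundle$oof[[bundle$best]]
  risk_w3 <- predict(bundle, d3$X)
  states <- fit_states(risk_w2, K = K, seed = seed)
  s_w2 <- assign_states(risk_w2, states)
  s_w3 <- assign_states(risk_w3, states)
  tm <- fit_transition(d2$X, s_w2, s_w3, K = K, model = transition_model,
                       folds = folds, seed = seed, nrounds = nrounds)
  om <- fit_outcome(d2$X, s_w2, structure(tm$oof_soft, cross_fitted = TRUE),
                    y, K = K, model = outcome_model, folds = folds,
                    seed = seed)
  structure(list(panel = pre$panel, panel_raw = panel, plan = pre$plan,
                 encoder = d2$encoder, X_w2 = d2$X, X_w3 = d3$X,
                 predictor = bundle, risk_w2 = risk_w2, risk_w3 = risk_w3,
                 states = states, s_w2 = s_w2, s_w3 = s_w3,
                 transition = tm, outcome = om,
                 case_threshold = case_threshold, seed = seed),
            class = "digital_twin")
}

#' @export
print.digital_twin <- function(x, ...) {
  cat("Digital twin (two-wave, single-step)\n")
  cat(sprintf("  cohort:      n = %d, wave-3 incidence %.3f\n",
              nrow(x$panel$w2), mean(x$panel_raw$outcome_w3)))
  cat(sprintf("  predictor:   %s (out-of-fold AUC %.3f)\n", x$predictor$best,
              max(x$predictor$metrics$auc)))
  cat(sprintf("  states:      K = %d, centroids %s (frozen at wave 2)\n",
              x$states$K, paste(sprintf("%.3f", x$states$centroids),
                                collapse = ", ")))
  cat(sprintf("  transition:  %s, accuracy %.3f\n", x$transition$model,
              x$transition$accuracy))
  cat(sprintf("  outcome:     %s, AUC %.3f\n", x$outcome$model, x$outcome$auc))
  invisible(x)
}

#' @export
summary.digital_twin <- function(object, ...) {
  x <- object
  print(x)
  cat("\nWave-2 state occupancy:\n")
  print(table(factor(x$s_w2, labels = x$states$labels)))
  cat("Wave-3 state occupancy (frozen centroids):\n")
  print(table(factor(x$s_w3, levels = seq_len(x$states$K),
                     labels = x$states$labels)))
  cat("\nPredictor metrics:\n")
  print.data.frame(x$predictor$metrics[, c("model", "accuracy", "auc",
                                           "pr_auc", "brier", "ece")],
                   digits = 3)
  invisible(x)
}

#' Predict from a fitted digital twin
#'
#' @param object A `digital_twin`.
#' @param type `"risk_w2"` (out-of-fold baseline risk), `"risk_w3"`
#'   (wave-3 risk under frozen wave-2 predictor), `"state_w2"`,
#'   `"state_w3"`, or `"outcome"` (outcome-model risk).
#' @param ... Unused.
#' @return Numeric or integer vector per participant.
#' @export
predict.digital_twin <- function(object, type = c("outcome", "risk_w2",
                                                  "risk_w3", "state_w2",
                                                  "state_w3"), ...) {
  type <- match.arg(type)
  switch(type,
         risk_w2 = object$risk_w2,
         risk_w3 = object$risk_w3,
         state_w2 = object$s_w2,
         state_w3 = object$s_w3,
         outcome = {
           soft <- predict(object$transition, object$X_w2, object$s_w2)
           predict(object$outcome, object$X_w2, object$s_w2, soft)
         })
}

#' Simulate what-if scenarios on a digital twin
#'
#' `simulate()` method wrapping [simulate_scenario()]; the engine is fully
#' deterministic, so `nsim`/`seed` are accepted for generic compatibility
#' but a given scenario always yields the identical result.
#'
#' @param object A `digital_twin`.
#' @param nsim Unused (deterministic engine).
#' @param seed Unused (deterministic engine).
#' @param scenario A `scenario_spec`.
#' @param ... Passed to [simulate_scenario()].
#' @return A `scenario_result`.
#' @export
simulate.digital_twin <- function(object, nsim = 1, seed = NULL, scenario,
                                  ...) {
  simulate_scenario(object, scenario, ...)
}
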