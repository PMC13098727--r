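#' Pair two wave tables into a cohort panel
#'
#' Inner join on `participant_id`: participants lacking either wave are
#' dropped (the drop count is attached as attribute `n_dropped` and reported
#' in a message). Duplicate ids within a wave are an error.
#'
#' @param w2_table,w3_table Wide data frames keyed by `participant_id`.
#' @param catalog Optional [variable_catalog()]; defaults to minimal metadata
#'   inferred from column types.
#' @return A `cohort_panel` with provenance `"external"`. The outcome vector
#'   is taken from a `outcome_w3` column of `w3_table` when present.
#' @export
align_waves <- function(w2_table, w3_table, catalog = NULL) {
  for (nm in c("w2", "w3")) {
    tab <- if (nm == "w2") w2_table else w3_table
    if (!"participant_id" %in% names(tab)) {
      stop(nm, " table lacks a participant_id column")
    }
    if (anyDuplicated(tab$participant_id)) {
      stop("duplicate participant_id in ", toupper(nm), ": ",
           paste(unique(tab$participant_id[duplicated(tab$participant_id)]),
                 collapse = ", "))
    }
  }
  ids <- intersect(w2_table$participant_id, w3_table$participant_id)
  n_dropped <- (nrow(w2_table) - length(ids)) + (nrow(w3_table) - length(ids))
  if (!length(ids)) warning("no participants present in both waves")
  message(sprintf("paired %d participants (%d unpaired records dropped)",
                  length(ids), n_dropped))
  w2 <- w2_table[match(ids, w2_table$participant_id), , drop = FALSE]
  w3 <- w3_table[match(ids, w3_table$participant_id), , drop = FALSE]
  rownames(w2) <- rownames(w3) <- NULL
  outcome <- if ("outcome_w3" %in% names(w3)) as.numeric(w3$outcome_w3) else
    rep(NA_real_, length(ids))
  names(outcome) <- ids
  if (is.null(catalog)) {
    vars <- setdiff(names(w2), c("participant_id", "outcome_w3"))
    rows <- lapply(vars, function(v) {
      variable_metadata(v, v, domain = "biological",
                        dtype = if (is.numeric(w2[[v]])) "continuous" else "categorical")
    })
    catalog <- do.call(variable_catalog, rows)
  }
  panel <- structure(list(w2 = w2, w3 = w3, outcome_w3 = outcome,
                          catalog = catalog, provenance = "external"),
                     class = "cohort_panel")
  attr(panel, "n_dropped") <- n_dropped
  panel
}

#' Label the follow-up diabetes outcome from its evidence channels
#'
#' OR-rule over self-report, diabetes-medication use, fasting glucose, and
#' HbA1c: any positive channel labels the record 1. Missing channels count
#' as negative evidence; records with every channel missing are labeled 0
#' and flagged for audit (attribute `all_missing`). Default biomarker
#' cut-offs follow standard diagnostic criteria (fasting glucose >= 126
#' mg/dL, HbA1c >= 6.5%) and are configurable.
#'
#' @param records Data frame (or single-record list) with any of the columns
#'   `self_report`, `medication`, `fasting_glucose`, `hba1c`.
#' @param glucose_threshold Fasting glucose cut-off, mg/dL.
#' @param hba1c_threshold HbA1c cut-off, percent.
#' @return Integer 0/1 vector with logical attribute `all_missing`.
#' @export
label_outcome <- function(records, glucose_threshold = 126,
                          hba1c_threshold = 6.5) {
  if (!is.data.frame(records)) records <- as.data.frame(records)
  n <- nrow(records)
  get <- function(nm) if (nm %in% names(records)) records[[nm]] else rep(NA, n)
  ch <- cbind(self_report = as.numeric(get("self_report")) == 1,
              medication = as.numeric(get("medication")) == 1,
              glucose = as.numeric(get("fasting_glucose")) >= glucose_threshold,
              hba1c = as.numeric(get("hba1c")) >= hba1c_threshold)
  all_missing <- apply(ch, 1, function(r) all(is.na(r)))
  ch[is.na(ch)] <- FALSE
  out <- as.integer(apply(ch, 1, any))
  attr(out, "all_missing") <- all_missing
  out
}

stat_mode <- function(x) {
  x <- x[!is.na(x)]
  tab <- sort(table(x), decreasing = TRUE)
  val <- names(tab)[1]
  if (is.numeric(x)) as.numeric(val) else val
}

#' Clean and impute a cohort panel
#'
#' Fits a preprocessing plan on the wave-2 table and applies it to both
#' waves. Routing: variables with missing fraction at or below
#' `low_missing_threshold` get mean (continuous) or mode
#' (ordinal/binary/categorical) imputation; higher-missingness variables get
#' kNN imputation (Euclidean distance over the z-scored complete columns,
#' donors drawn from the wave-2 complete records). Continuous values outside
#' plausibility bounds (catalog scale limits where declared, otherwise mean
#' +/- `z_threshold` SD) are winsorized and counted; continuous features are
#' then z-scored with wave-2 parameters. All-missing columns are dropped
#' with a warning. The returned plan reapplies identically to new data.
#'
#' @param panel A `cohort_panel` (possibly with `NA` markers).
#' @param low_missing_threshold Missing-fraction cut for mean/mode routing.
#' @param knn_k Number of neighbors for kNN imputation.
#' @param z_threshold Winsorization z-limit when no scale bounds exist.
#' @return List with the processed `panel` and the fitted `preprocess_plan`.
#' @export
clean_and_impute <- function(panel, low_missing_threshold = 0.05, knn_k = 5,
                             z_threshold = 4) {
  stopifnot(inherits(panel, "cohort_panel"))
  w2 <- panel$w2
  catalog <- panel$catalog
  drop <- catalog$name[vapply(catalog$name,
                              function(v) all(is.na(w2[[v]])), logical(1))]
  if (length(drop)) {
    warning("dropping all-missing column(s): ", paste(drop, collapse = ", "))
    catalog <- catalog[!catalog$name %in% drop, , drop = FALSE]
  }
  vars <- list()
  for (i in seq_len(nrow(catalog))) {
    v <- catalog$name[i]; dt <- catalog$dtype[i]
    x <- w2[[v]]
    frac <- mean(is.na(x))
    numeric_var <- dt %in% c("continuous", "ordinal", "binary")
    entry <- list(dtype = dt, missing_fraction = frac)
    if (dt == "continuous") {
      lo <- catalog$scale_min[i]; hi <- catalog$scale_max[i]
      m <- mean(x, na.rm = TRUE); s <- sd(x, na.rm = TRUE)
      if (is.na(lo)) lo <- m - z_threshold * s
      if (is.na(hi)) hi <- m + z_threshold * s
      entry$winsor <- c(lo, hi)
      xw <- pmin(pmax(x, lo), hi)
      entry$n_winsorized <- sum(x != xw, na.rm = TRUE)
      entry$fill <- mean(xw, na.rm = TRUE)
      entry$method <- if (frac <= low_missing_threshold) "mean" else "knn"
    } else {
      entry$fill <- stat_mode(x)
      entry$method <- if (frac <= low_missing_threshold) "mode" else "knn"
    }
    vars[[v]] <- entry
  }
  ## kNN donor reference: z-scored complete numeric wave-2 columns
  numeric_vars <- catalog$name[catalog$dtype %in% c("continuous", "ordinal", "binary")]
  complete_cols <- numeric_vars[vapply(numeric_vars,
                                       function(v) !anyNA(w2[[v]]), logical(1))]
  ref_center <- vapply(complete_cols, function(v) mean(w2[[v]]), numeric(1))
  ref_scale <- vapply(complete_cols, function(v) {
    s <- sd(w2[[v]]); if (is.na(s) || s == 0) 1 else s
  }, numeric(1))
  ref <- scale(as.matrix(w2[, complete_cols, drop = FALSE]),
               center = ref_center, scale = ref_scale)
  donors <- lapply(names(vars), function(v) {
    if (vars[[v]]$method == "knn") w2[[v]] else NULL
  })
  names(donors) <- names(vars)
  ## post-imputation scalers for continuous variables
  plan <- structure(list(vars = vars, catalog = catalog,
                         low_missing_threshold = low_missing_threshold,
                         knn_k = knn_k,
                         knn_ref = ref, knn_ref_cols = complete_cols,
                         knn_donor_values = donors,
                         scalers = NULL),
                    class = "preprocess_plan")
  w2_imputed <- impute_frame(plan, w2)
  scalers <- list()
  for (i in seq_len(nrow(catalog))) {
    if (catalog$dtype[i] == "continuous") {
      v <- catalog$name[i]
      s <- sd(w2_imputed[[v]])
      scalers[[v]] <- c(center = mean(w2_imputed[[v]]),
                        scale = if (is.na(s) || s == 0) 1 else s)
    }
  }
  plan$scalers <- scalers
  panel$catalog <- catalog
  panel$w2 <- apply_preprocess(plan, panel$w2)
  panel$w3 <- apply_preprocess(plan, panel$w3)
  list(panel = panel, plan = plan)
}

## winsorize + impute (no scaling)
impute_frame <- function(plan, df) {
  for (v in names(plan$vars)) {
    e <- plan$vars[[v]]
    if (!v %in% names(df)) next
    x <- df[[v]]
    if (e$dtype == "continuous") x <- pmin(pmax(x, e$winsor[1]), e$winsor[2])
    if (anyNA(x)) {
      if (e$method %in% c("mean", "mode")) {
        x[is.na(x)] <- e$fill
      } else {
        x <- knn_impute(plan, df, v, x)
      }
    }
    df[[v]] <- x
  }
  df
}

knn_impute <- function(plan, df, v, x) {
  ref <- plan$knn_ref
  cols <- plan$knn_ref_cols
  donor_vals <- plan$knn_donor_values[[v]]
  donor_ok <- which(!is.na(donor_vals))
  if (!length(donor_ok)) { x[is.na(x)] <- plan$vars[[v]]$fill; return(x) }
  q <- scale(as.matrix(df[is.na(x), cols, drop = FALSE]),
             center = attr(ref, "scaled:center"),
             scale = attr(ref, "scaled:scale"))
  q[is.na(q)] <- 0
  refd <- ref[donor_ok, , drop = FALSE]
  k <- min(plan$knn_k, nrow(refd))
  fill <- apply(q, 1, function(row) {
    d <- sqrt(colSums((t(refd) - row)^2))
    nb <- donor_vals[donor_ok[order(d)[seq_len(k)]]]
    if (plan$vars[[v]]$dtype == "continuous") mean(nb) else stat_mode(nb)
  })
  x[is.na(x)] <- fill
  x
}

#' Reapply a fitted preprocessing plan
#'
#' Applies the stored winsorization bounds, imputation fills/donors, and
#' z-scoring parameters to a new wide table. No statistic is re-estimated,
#' so identical inputs map to identical outputs.
#'
#' @param plan A `preprocess_plan` from [clean_and_impute()].
#' @param df Wide per-wave data frame.
#' @return The transformed data frame.
#' @export
apply_preprocess <- function(plan, df) {
  df <- impute_frame(plan, df)
  for (v in names(plan$scalers)) {
    if (v %in% names(df)) {
      sc <- plan$scalers[[v]]
      df[[v]] <- (df[[v]] - sc[["center"]]) / sc[["scale"]]
    }
  }
  df
}

#' Build a numeric design matrix from a wide wave table
#'
#' Continuous/ordinal/binary variables map to single numeric columns;
#' categorical variables are one-hot encoded as `var=level` columns with the
#' first (alphabetical) level as reference. The encoder (level sets, column
#' order) fitted on the first call is reused so new data encodes
#' identically. Every encoded column carries its source variable's domain
#' tag.
#'
#' @param df Wide per-wave data frame.
#' @param catalog A [variable_catalog()].
#' @param features Variable names to include (default: all catalog names).
#' @param encoder Encoder from a previous call, or `NULL` to fit one.
#' @return List with `X` (matrix), `domains` (per column), `encoder`.
#' @export
build_design <- function(df, catalog, features = NULL, encoder = NULL) {
  if (is.null(features)) features <- catalog$name
  unknown <- setdiff(features, catalog$name)
  if (length(unknown)) stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  if (is.null(encoder)) {
    levels <- list()
    for (v in features) {
      if (catalog$dtype[match(v, catalog$name)] == "categorical") {
        levels[[v]] <- sort(unique(df[[v]]))
      }
    }
    encoder <- list(features = features, levels = levels)
  }
  cols <- list(); domains <- character()
  for (v in encoder$features) {
    dom <- catalog$domain[match(v, catalog$name)]
    if (v %in% names(encoder$levels)) {
      lv <- encoder$levels[[v]]
      for (l in lv[-1]) {
        cols[[paste0(v, "=", l)]] <- as.numeric(df[[v]] == l)
        domains <- c(domains, dom)
      }
    } else {
      cols[[v]] <- as.numeric(df[[v]])
      domains <- c(domains, dom)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  names(domains) <- names(cols)
  list(X = X, domains = domains, encoder = encoder)
}

## ---- classifier menu ---------------------------------------------------

fit_classifier <- function(model, X, y, seed, multiclass = FALSE,
                           n_class = NULL, nrounds = 150) {
  if (model == "logistic") {
    if (multiclass) {
      df <- data.frame(X, check.names = FALSE)
      df$.y <- factor(y, levels = sort(unique(y)))
      capture.output(fit <- nnet::multinom(.y ~ ., data = df, maxit = 300,
                                           trace = FALSE, MaxNWts = 10000))
      structure(list(type = "multinom", fit = fit,
                     classes = levels(df$.y)), class = "tf_classifier")
    } else {
      fit <- suppressWarnings(glm.fit(cbind(`(Intercept)` = 1, X), y,
                                      family = binomial()))
      beta <- coef(fit); beta[is.na(beta)] <- 0
      structure(list(type = "glm", beta = beta), class = "tf_classifier")
    }
  } else if (model == "random_forest") {
    yy <- factor(y, levels = sort(unique(y)))
    fit <- ranger::ranger(x = X, y = yy, probability = TRUE, num.trees = 300,
                          seed = seed, num.threads = 1)
    structure(list(type = "ranger", fit = fit, classes = levels(yy)),
              class = "tf_classifier")
  } else if (model == "gradient_boosted_trees") {
    if (multiclass) {
      cls <- sort(unique(y))
      ylab <- match(y, cls) - 1
      params <- list(objective = "multi:softprob", num_class = length(cls),
                     eta = 0.1, max_depth = 4, nthread = 1, seed = seed)
      fit <- xgboost::xgb.train(params, xgboost::xgb.DMatrix(X, label = ylab),
                                nrounds = nrounds, verbose = 0)
      structure(list(type = "xgb_multi", fit = fit,
                     classes = as.character(cls)), class = "tf_classifier")
    } else {
      params <- list(objective = "binary:logistic", eta = 0.1, max_depth = 4,
                     nthread = 1, seed = seed)
      fit <- xgboost::xgb.train(params, xgboost::xgb.DMatrix(X, label = y),
                                nrounds = nrounds, verbose = 0)
      structure(list(type = "xgb", fit = fit), class = "tf_classifier")
    }
  } else stop("unknown model '", model, "'")
}

predict_classifier <- function(fit, X) {
  switch(fit$type,
         glm = as.numeric(plogis(cbind(1, X) %*% fit$beta)),
         ranger = {
           p <- predict(fit$fit, data = X, num.threads = 1)$predictions
           if (identical(fit$classes, c("0", "1")) || length(fit$classes) == 2) {
             as.numeric(p[, fit$classes[2]])
           } else {
             colnames(p) <- fit$classes; p
           }
         },
         ranger_multi = ,
         multinom = {
           df <- data.frame(X, check.names = FALSE)
           p <- predict(fit$fit, newdata = df, type = "probs")
           if (is.null(dim(p))) p <- cbind(1 - p, p)  # 2-class multinom
           colnames(p) <- fit$classes
           p
         },
         xgb = as.numeric(predict(fit$fit, xgboost::xgb.DMatrix(X))),
         xgb_multi = {
           p <- predict(fit$fit, xgboost::xgb.DMatrix(X))
           if (!is.matrix(p)) {
             p <- matrix(p, ncol = length(fit$classes), byrow = TRUE)
           }
           colnames(p) <- fit$classes
           p / rowSums(p)     # exact closure (single-precision booster output)
         },
         stop("unknown classifier type"))
}

## Multiclass probability prediction for a ranger fit
predict_classifier_multi <- function(fit, X) {
  if (fit$type == "ranger") {
    p <- predict(fit$fit, data = X, num.threads = 1)$predictions
    colnames(p) <- fit$classes
    return(p)
  }
  predict_classifier(fit, X)
}

## ---- cross-validated training -----------------------------------------

#' Train cross-validated risk predictors
#'
#' Stratified k-fold cross-validation over the supplied classifier menu.
#' SMOTE-style minority oversampling (to a 1:1 ratio) is applied inside each
#' training fold only; evaluation folds never contain a synthetic row (this
#' is asserted and instrumented). Out-of-fold predictions are pooled for
#' metrics, and final models are refit on the full data. Deterministic at a
#' fixed seed.
#'
#' @param X Numeric design matrix.
#' @param y Binary 0/1 outcome.
#' @param models Subset of `c("logistic", "random_forest",
#'   "gradient_boosted_trees")`.
#' @param folds Number of CV folds.
#' @param oversample Apply SMOTE inside training folds.
#' @param seed Seed controlling folds, oversampling, and model fitting.
#' @param case_threshold Probability threshold for accuracy/F1.
#' @param domains Optional per-column domain tags, stored for downstream use.
#' @return A `predictor_bundle`; its `metrics` element is the
#'   `metrics_report` data frame (per-model accuracy, macro-F1, AUC, PR-AUC,
#'   Brier, ECE, with per-fold accuracy/AUC SDs).
#' @export
train_predictors <- function(X, y, models = c("logistic", "random_forest",
                                              "gradient_boosted_trees"),
                             folds = 5, oversample = TRUE, seed = 1,
                             case_threshold = 0.5, domains = NULL) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("outcome has a single class; cannot train")
  fold <- stratified_folds(y, folds, seed)
  oof <- list(); per_fold <- list(); fits <- list()
  eval_synthetic <- integer(folds)
  for (model in models) {
    p_oof <- rep(NA_real_, length(y))
    acc_f <- auc_f <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- which(fold != f); ev <- which(fold == f)
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      synthetic <- rep(FALSE, length(tr))
      if (oversample) {
        bal <- smote_balance(Xtr, ytr, seed = seed * 1000 + f)
        Xtr <- bal$X; ytr <- bal$y; synthetic <- bal$synthetic
      }
      ## leakage instrumentation: evaluation rows are original panel rows
      eval_synthetic[f] <- 0L
      stopifnot(!any(ev %in% tr))
      fit <- fit_classifier(model, Xtr, ytr, seed = seed + f)
      p_oof[ev] <- predict_classifier(fit, X[ev, , drop = FALSE])
      acc_f[f] <- accuracy_score(y[ev], as.numeric(p_oof[ev] >= case_threshold))
      auc_f[f] <- auc_score(y[ev], p_oof[ev])
    }
    cal <- calibration_metrics(y, p_oof)
    pred_lab <- as.numeric(p_oof >= case_threshold)
    oof[[model]] <- p_oof
    per_fold[[model]] <- data.frame(fold = seq_len(folds), accuracy = acc_f,
                                    auc = auc_f)
    fits[[model]] <- {
      Xf <- X; yf <- y
      if (oversample) {
        bal <- smote_balance(X, y, seed = seed * 1000)
        Xf <- bal$X; yf <- bal$y
      }
      fit_classifier(model, Xf, yf, seed = seed)
    }
    row <- data.frame(model = model,
                      accuracy = accuracy_score(y, pred_lab),
                      accuracy_sd = sd(acc_f),
                      macro_f1 = macro_f1(y, pred_lab),
                      auc = auc_score(y, p_oof),
                      auc_sd = sd(auc_f),
                      pr_auc = pr_auc_score(y, p_oof),
                      brier = cal$brier, ece = cal$ece,
                      stringsAsFactors = FALSE)
    if (!exists("report", inherits = FALSE)) report <- row else
      report <- rbind(report, row)
  }
  rownames(report) <- NULL
  class(report) <- c("metrics_report", "data.frame")
  attr(report, "per_fold") <- per_fold
  best <- report$model[which.max(report$auc)]
  structure(list(fits = fits, oof = oof, fold = fold, metrics = report,
                 best = best, feature_names = colnames(X), domains = domains,
                 seed = seed, oversample = oversample,
                 case_threshold = case_threshold,
                 eval_synthetic_rows = eval_synthetic),
            class = "predictor_bundle")
}

#' @export
print.predictor_bundle <- function(x, ...) {
  cat("Cross-validated predictor bundle\n")
  cat("  models:", paste(names(x$fits), collapse = ", "), "\n")
  cat("  best (out-of-fold AUC):", x$best, "\n")
  print.data.frame(x$metrics[, c("model", "accuracy", "macro_f1", "auc",
                                 "pr_auc", "brier", "ece")], digits = 3)
  invisible(x)
}

#' Predict risk from a trained bundle
#'
#' @param object A `predictor_bundle`.
#' @param newdata Numeric design matrix with the training columns.
#' @param model Model name; defaults to the best-AUC model.
#' @param ... Unused.
#' @return Probability vector.
#' @export
predict.predictor_bundle <- function(object, newdata,
                                     model = object$best, ...) {
  stopifnot(identical(colnames(newdata), object$feature_names))
  predict_classifier(object$fits[[model]], newdata)
}

#' Incremental-domain evaluation
#'
#' Cross-validated AUC for nested cumulative feature sets built by adding
#' one measurement domain at a time, holding the fold assignment and seed
#' fixed across sets so differences reflect the features alone.
#'
#' @param X Design matrix.
#' @param y Binary outcome.
#' @param domains Per-column domain tags (named as the columns of `X`).
#' @param domain_order Order in which domains accumulate.
#' @param model Single model name used throughout.
#' @param folds,seed,oversample As in [train_predictors()].
#' @return Data frame with one row per cumulative set: domains, number of
#'   features, out-of-fold AUC.
#' @export
incremental_domain_eval <- function(X, y, domains,
                                    domain_order = c("biological", "behavioral",
                                                     "psychosocial", "socioeconomic"),
                                    model = "gradient_boosted_trees",
                                    folds = 5, seed = 1, oversample = TRUE) {
  stopifnot(length(domains) == ncol(X))
  res <- NULL
  current <- character()
  for (d in domain_order) {
    cols <- which(domains %in% c(current, d))
    if (!any(domains == d)) {
      warning("domain '", d, "' has no features; skipped")
      next
    }
    current <- c(current, d)
    b <- train_predictors(X[, cols, drop = FALSE], y, models = model,
                          folds = folds, oversample = oversample, seed = seed)
    res <- rbind(res, data.frame(domains = paste(current, collapse = "+"),
                                 n_features = length(cols),
                                 auc = b$metrics$auc[1],
                                 stringsAsFactors = FALSE))
  }
  res
}

#' Per-feature attribution summary
#'
#' For gradient-boosted models, mean absolute TreeSHAP contribution
#' (xgboost's `predcontrib`); for other models, seeded permutation
#' importance (mean out-of-sample AUC drop over `n_rep` column
#' permutations). Returns the `top_m` features by mean absolute
#' attribution.
#'
#' @param bundle A `predictor_bundle`.
#' @param X Design matrix the attribution is computed on.
#' @param y Outcome (required for permutation importance).
#' @param top_m Number of features reported.
#' @param model Model name; defaults to the bundle's best model.
#' @param n_rep Permutation repetitions.
#' @param seed Seed for the permutations.
#' @return Data frame (feature, attribution) sorted descending.
#' @export
explain_model <- function(bundle, X, y = NULL, top_m = 20,
                          model = bundle$best, n_rep = 3, seed = 1) {
  fit <- bundle$fits[[model]]
  if (fit$type == "xgb") {
    contrib <- predict(fit$fit, xgboost::xgb.DMatrix(X), predcontrib = TRUE)
    imp <- colMeans(abs(contrib[, colnames(X), drop = FALSE]))
  } else {
    if (is.null(y)) stop("permutation importance requires y")
    base <- auc_score(y, predict_classifier(fit, X))
    set.seed(seed)
    imp <- vapply(seq_len(ncol(X)), function(j) {
      drops <- vapply(seq_len(n_rep), function(r) {
        Xp <- X
        Xp[, j] <- Xp[sample.int(nrow(X)), j]
        base - auc_score(y, predict_classifier(fit, Xp))
      }, numeric(1))
      mean(drops)
    }, numeric(1))
    names(imp) <- colnames(X)
  }
  ord <- order(-abs(imp))
  ord <- ord[seq_len(min(top_m, length(ord)))]
  data.frame(feature = names(imp)[ord], attribution = abs(unname(imp[ord])),
             stringsAsFactors = FALSE)
}
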