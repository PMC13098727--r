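test_that("wave alignment keeps the id intersection and rejects duplicates", {
  w2 <- data.frame(participant_id = 1:5, a = rnorm(5))
  w3 <- data.frame(participant_id = 3:7, a = rnorm(5))
  suppressMessages(p <- align_waves(w2, w3))
  expect_equal(nrow(p$w2), 3)
  expect_identical(p$w2$participant_id, 3:5)
  expect_equal(attr(p, "n_dropped"), 4)
  suppressMessages(expect_warning(
    align_waves(w2, data.frame(participant_id = 10:12, a = rnorm(3))),
    "no participants"))
  expect_error(suppressMessages(
    align_waves(rbind(w2, w2[1, ]), w3)), "duplicate")
})

test_that("outcome labeling applies the OR rule over evidence channels", {
  rec <- data.frame(self_report = c(1, 0, NA, NA, NA),
                    medication = c(NA, 0, NA, NA, 1),
                    fasting_glucose = c(NA, 100, 130, NA, NA),
                    hba1c = c(NA, 5.0, NA, NA, NA))
  lab <- label_outcome(rec)
  expect_equal(as.integer(lab), c(1L, 0L, 1L, 0L, 1L))
  expect_identical(attr(lab, "all_missing"), c(FALSE, FALSE, FALSE, TRUE, FALSE))
  # configurable thresholds
  expect_equal(as.integer(label_outcome(data.frame(fasting_glucose = 130),
                                        glucose_threshold = 140)), 0L)
  expect_equal(as.integer(label_outcome(data.frame(hba1c = 6.5))), 1L)
})

test_that("mean/mode imputation fills exactly as computed by hand", {
  catalog <- variable_catalog(
    variable_metadata("x", "x", "biological", "continuous"),
    variable_metadata("c", "c", "administrative", "categorical"))
  w2 <- data.frame(participant_id = 1:4, x = c(1, 2, NA, 3),
                   c = c("a", "a", "b", NA), stringsAsFactors = FALSE)
  panel <- structure(list(w2 = w2, w3 = w2, outcome_w3 = c(0, 1, 0, 1),
                          catalog = catalog, provenance = "external"),
                     class = "cohort_panel")
  out <- clean_and_impute(panel, low_missing_threshold = 0.5)
  plan <- out$plan
  expect_equal(plan$vars$x$method, "mean")
  expect_equal(plan$vars$x$fill, 2)           # mean of 1, 2, 3
  expect_equal(plan$vars$c$fill, "a")         # mode
  # z-scored continuous: back out the raw fill from the stored scaler
  sc <- plan$scalers$x
  raw <- out$panel$w2$x * sc[["scale"]] + sc[["center"]]
  expect_equal(raw, c(1, 2, 2, 3))
  expect_equal(out$panel$w2$c, c("a", "a", "b", "a"))
})

test_that("kNN imputation with k = 1 equals the brute-force nearest donor", {
  catalog <- variable_catalog(
    variable_metadata("a", "a", "biological", "continuous"),
    variable_metadata("b", "b", "biological", "continuous"),
    variable_metadata("v", "v", "biological", "continuous"))
  set.seed(5)
  n <- 15
  w2 <- data.frame(participant_id = 1:n, a = rnorm(n), b = rnorm(n),
                   v = rnorm(n))
  w2$v[c(2, 9)] <- NA
  panel <- structure(list(w2 = w2, w3 = w2, outcome_w3 = rbinom(n, 1, 0.5),
                          catalog = catalog, provenance = "external"),
                     class = "cohort_panel")
  out <- clean_and_impute(panel, low_missing_threshold = 0.01, knn_k = 1)
  # oracle: standardize complete columns, scan all donors
  za <- scale(w2$a); zb <- scale(w2$b)
  donors <- which(!is.na(w2$v))
  for (i in c(2, 9)) {
    d <- sqrt((za[donors] - za[i])^2 + (zb[donors] - zb[i])^2)
    expected_raw <- w2$v[donors[which.min(d)]]
    sc <- out$plan$scalers$v
    got_raw <- out$panel$w2$v[i] * sc[["scale"]] + sc[["center"]]
    expect_equal(got_raw, expected_raw)
  }
})

test_that("all-missing columns are dropped with a warning", {
  catalog <- variable_catalog(
    variable_metadata("x", "x", "biological", "continuous"),
    variable_metadata("z", "z", "biological", "continuous"))
  w2 <- data.frame(participant_id = 1:3, x = c(1, 2, 3), z = NA_real_)
  panel <- structure(list(w2 = w2, w3 = w2, outcome_w3 = c(0, 1, 0),
                          catalog = catalog, provenance = "external"),
                     class = "cohort_panel")
  expect_warning(out <- clean_and_impute(panel), "all-missing")
  expect_false("z" %in% out$plan$catalog$name)
})

test_that("calibration metrics match closed forms and hand arithmetic", {
  # perfect probabilities
  y <- c(0, 1, 1, 0)
  expect_equal(calibration_metrics(y, y), list(brier = 0, ece = 0))
  # constant 1/2 on a balanced sample
  m <- calibration_metrics(c(0, 1, 0, 1), rep(0.5, 4))
  expect_equal(m$brier, 0.25)
  expect_equal(m$ece, 0)
  # four hand-listed pairs: Brier = mean((p-y)^2); ECE by bin arithmetic
  y4 <- c(1, 0, 1, 0); p4 <- c(0.9, 0.8, 0.35, 0.12)
  m4 <- calibration_metrics(y4, p4, n_bins = 10)
  expect_equal(m4$brier, mean((p4 - y4)^2))
  # bins: 0.9 -> (0.8,0.9], 0.8 -> (0.7,0.8], 0.35 -> (0.3,0.4], 0.12 -> (0.1,0.2]
  expect_equal(m4$ece, (abs(1 - 0.9) + abs(0 - 0.8) + abs(1 - 0.35) +
                          abs(0 - 0.12)) / 4)
  expect_error(calibration_metrics(c(0, 1), 0.5), "length")
})

test_that("rank AUC and average precision match brute-force oracles", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2)   # rounding forces ties
    expect_equal(auc_score(y, p), auc_bruteforce(y, p), tolerance = 1e-12)
  }
  # hand PR-AUC: scores 0.9(+), 0.8(-), 0.7(+), precision 1/1 then 2/3
  expect_equal(pr_auc_score(c(1, 0, 1), c(0.9, 0.8, 0.7)), (1 + 2 / 3) / 2)
  # macro-F1 hand case
  expect_equal(macro_f1(c(1, 1, 0, 0), c(1, 0, 0, 0)),
               mean(c(2 * 1 / (2 * 1 + 0 + 1), 2 * 2 / (2 * 2 + 1 + 0))))
})

test_that("training is leakage-safe, separable data is learned, nulls stay at chance", {
  set.seed(20)
  n <- 400
  x <- rnorm(n)
  y <- as.numeric(x > 0)                       # linearly separable
  X <- cbind(x = x, junk = rnorm(n))
  b <- train_predictors(X, y, models = "logistic", folds = 5, seed = 1)
  expect_equal(b$metrics$auc[1], 1.0)
  expect_true(all(b$eval_synthetic_rows == 0))  # no synthetic rows in eval folds
  # permutation null at n = 2000
  set.seed(21)
  n <- 2000
  X2 <- cbind(a = rnorm(n), b = rnorm(n))
  y2 <- sample(rep(0:1, each = n / 2))
  b2 <- train_predictors(X2, y2, models = "logistic", folds = 5, seed = 2)
  expect_lt(abs(b2$metrics$auc[1] - 0.5), 0.05)
  # single-class outcome is rejected
  expect_error(train_predictors(X2, rep(1, n), models = "logistic"),
               "single class")
})

test_that("training is deterministic at a fixed seed across the model menu", {
  p <- tiny_panel(n = 250, seed = 6)
  pre <- clean_and_impute(p)
  d <- build_design(pre$panel$w2, pre$panel$catalog)
  y <- as.numeric(p$outcome_w3)
  b1 <- train_predictors(d$X, y, folds = 3, seed = 9)
  b2 <- train_predictors(d$X, y, folds = 3, seed = 9)
  expect_equal(b1$metrics, b2$metrics)
  expect_identical(b1$oof, b2$oof)
})

test_that("incremental domain evaluation is a reduction for one domain and gains with signal", {
  p <- tiny_panel(n = 2000, seed = 14)
  pre <- clean_and_impute(p)
  d <- build_design(pre$panel$w2, pre$panel$catalog)
  y <- as.numeric(p$outcome_w3)
  res <- incremental_domain_eval(d$X, y, d$domains, model = "logistic",
                                 folds = 3, seed = 4)
  expect_equal(nrow(res), 4)
  # the full multidomain set should not underperform biology alone (signal
  # exists in all four domains); allow CV noise
  expect_gt(res$auc[4], res$auc[1] - 0.02)
  # single-domain order reduces to train_predictors on that subset
  bio <- which(d$domains == "biological")
  b <- train_predictors(d$X[, bio, drop = FALSE], y, models = "logistic",
                        folds = 3, seed = 4)
  one <- incremental_domain_eval(d$X, y, d$domains, domain_order = "biological",
                                 model = "logistic", folds = 3, seed = 4)
  expect_equal(one$auc[1], b$metrics$auc[1])
  # unknown domain in the order is skipped with a warning
  expect_warning(incremental_domain_eval(d$X, y, d$domains,
                                         domain_order = c("biological", "imaging"),
                                         model = "logistic", folds = 3,
                                         seed = 4), "imaging")
})

test_that("attribution ranks the only informative feature first", {
  set.seed(30)
  n <- 600
  X <- cbind(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  y <- rbinom(n, 1, plogis(2 * X[, "signal"]))
  b <- train_predictors(X, y, models = "gradient_boosted_trees", folds = 3,
                        seed = 3, oversample = FALSE)
  imp <- explain_model(b, X, y)
  expect_equal(imp$feature[1], "signal")
  # permutation-importance path agrees for the linear model
  bl <- train_predictors(X, y, models = "logistic", folds = 3, seed = 3,
                         oversample = FALSE)
  imp_l <- explain_model(bl, X, y, seed = 8)
  expect_equal(imp_l$feature[1], "signal")
})

test_that("additive logistic attribution ordering follows |coef x SD|", {
  set.seed(31)
  n <- 4000
  X <- cbind(big = rnorm(n, sd = 2), mid = rnorm(n, sd = 1),
             small = rnorm(n, sd = 1))
  # coef * SD: big 2.0, mid 1.0, small 0.2
  y <- rbinom(n, 1, plogis(1.0 * X[, "big"] + 1.0 * X[, "mid"] +
                             0.2 * X[, "small"]))
  b <- train_predictors(X, y, models = "logistic", folds = 3, seed = 5,
                        oversample = FALSE)
  imp <- explain_model(b, X, y, seed = 9)
  expect_identical(imp$feature, c("big", "mid", "small"))
})
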