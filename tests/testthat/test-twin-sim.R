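# Three tight clumps of predicted risk anchored near published state means
# (about 0.03 / 0.28 / 0.93), with the low stratum holding most of the mass.
three_clump_risks <- function(n = 1500, seed = 42,
                              centers = c(0.03, 0.28, 0.93),
                              weights = c(0.79, 0.10, 0.11), sd = 0.015) {
  set.seed(seed)
  g <- sample(1:3, n, replace = TRUE, prob = weights)
  pmin(pmax(rnorm(n, centers[g], sd), 0), 1)
}

test_that("state fitting recovers tight clumps and enforces preconditions", {
  r <- three_clump_risks()
  m <- fit_states(r, K = 3, seed = 1)
  expect_s3_class(m, "risk_state_model")
  expect_false(is.unsorted(m$centroids, strictly = TRUE))
  for (k in 1:3) {
    clump <- c(0.03, 0.28, 0.93)[k]
    expect_lt(abs(m$centroids[k] - clump), 0.02)
  }
  expect_identical(m$labels, c("low", "medium", "high"))
  expect_error(fit_states(r, K = 1), "at least 2")
  expect_error(fit_states(c(0.1, 0.1, 0.1), K = 3), "distinct")
  expect_error(fit_states(c(-0.1, 0.5), K = 2), "\\[0, 1\\]")
  # deterministic: identical runs give identical centroids
  expect_identical(fit_states(r, 3, seed = 7)$centroids, m$centroids)
})

test_that("1-D k-means equals the exhaustive contiguous-partition optimum", {
  set.seed(2)
  for (rep in 1:6) {
    n <- sample(20:60, 1)
    K <- sample(2:4, 1)
    x <- runif(n)
    m <- fit_states(x, K)
    expect_equal(m$sse, contiguous_partition_sse(x, K), tolerance = 1e-9)
    # centroids are the within-cluster means of its own assignment
    for (k in seq_len(K)) {
      expect_equal(m$centroids[k], mean(x[m$assignment == k]))
    }
  }
})

test_that("state assignment is nearest-centroid with a lower-state tie-break", {
  m <- fit_states(three_clump_risks(600, seed = 3), K = 3)
  expect_equal(assign_states(0, m)[1], 1L)
  expect_equal(assign_states(1, m)[1], 3L)
  # exact midpoint goes to the lower-risk state
  mid <- (m$centroids[1] + m$centroids[2]) / 2
  expect_equal(assign_states(mid, m)[1], 1L)
  # oracle equivalence: brute-force argmin scan over 1000 random risks
  set.seed(4)
  r <- runif(1000)
  got <- assign_states(r, m)
  oracle <- vapply(r, function(x) which.min(abs(x - m$centroids)), integer(1))
  expect_identical(as.integer(got), oracle)
  expect_error(assign_states(1.2, m), "\\[0, 1\\]")
})

test_that("frozen centroids are untouched by later assignment", {
  m <- fit_states(three_clump_risks(400, seed = 5), K = 3)
  h <- serialize(m$centroids, NULL)
  invisible(assign_states(runif(500), m))
  expect_identical(serialize(m$centroids, NULL), h)
})

test_that("high-risk union accumulates descending centroids to the reference size", {
  fake <- structure(list(K = 4, centroids = c(0.1, 0.4, 0.7, 0.95),
                         labels = paste0("state", 1:4),
                         sizes = c(2000L, 800L, 130L, 100L)),
                    class = "risk_state_model")
  # descending-centroid sizes are 100, 130, 800, 2000
  expect_identical(high_risk_union(fake, 220), c(4L, 3L))   # 100+130 >= 220
  expect_identical(high_risk_union(fake, 100), 4L)
  expect_identical(high_risk_union(fake, 0), 4L)            # non-empty guard
  expect_error(high_risk_union(fake, 5000), "exceeds")
  # K = 3 identity: reference equal to the top-cluster size
  m3 <- fit_states(three_clump_risks(500, seed = 6), 3)
  expect_identical(high_risk_union(m3, m3$sizes[3]), 3L)
})

test_that("jaccard overlap has its closed-form values", {
  expect_equal(jaccard_overlap(c(1, 2), c(2, 3)), 1 / 3)
  expect_equal(jaccard_overlap(1:5, 1:5), 1)
  expect_equal(jaccard_overlap(1:3, 4:6), 0)
  expect_equal(jaccard_overlap(integer(0), integer(0)), 1)
})

test_that("copy dynamics are learned perfectly by the transition model", {
  set.seed(8)
  n <- 1500
  s2 <- sample(1:3, n, replace = TRUE)
  X <- cbind(f1 = rnorm(n), f2 = rnorm(n))
  tm <- fit_transition(X, s2, s2, K = 3, model = "gradient_boosted_trees",
                       folds = 5, seed = 1, nrounds = 250)
  expect_equal(tm$accuracy, 1.0)
  expect_gte(tm$avg_log_likelihood, -0.01)
  # probability conservation
  p <- predict(tm, X, s2)
  expect_equal(unname(rowSums(p)), rep(1, n), tolerance = 1e-9)
})

test_that("perfect one-hot probabilistic predictions give zero log loss", {
  p <- diag(3)[c(1, 2, 3, 1), ]
  colnames(p) <- 1:3
  s <- c(1L, 2L, 3L, 1L)
  idx <- cbind(seq_along(s), s)
  expect_equal(mean(log(p[idx])), 0)
})

test_that("the outcome model demands cross-fitted soft states and separates perfectly", {
  set.seed(9)
  n <- 900
  s2 <- sample(1:3, n, replace = TRUE)
  s3 <- sample(1:3, n, replace = TRUE)
  X <- cbind(f = rnorm(n))
  soft <- diag(3)[s3, ]
  colnames(soft) <- 1:3
  y <- as.numeric(s3 == 3)               # outcome determined by next state
  expect_error(fit_outcome(X, s2, soft, y), "leakage")
  om <- fit_outcome(X, s2, structure(soft, cross_fitted = TRUE), y,
                    K = 3, folds = 3, seed = 2)
  expect_equal(om$auc, 1.0)
})

test_that("scenario application matches hand-computed perturbations", {
  p <- tiny_panel(n = 60, seed = 10)
  # pin a participant to the published worked example: BMI 29.6, weight 200
  p$w2$weight_lbs[1] <- 200
  p$w2$bmi[1] <- 29.6
  sc <- read_scenario(system.file("extdata", "scenario_weight10.json",
                                  package = "twinforge"))
  q <- apply_scenario(p, sc)
  expect_equal(q$w2$weight_lbs[1], 180)
  expect_equal(q$w2$bmi[1], 26.64)
  # untouched variables bit-identical
  expect_identical(q$w2$age, p$w2$age)
  expect_identical(q$w3, p$w3)
  # ordinal shift clamps at the scale maximum
  p$w2$physical_activity[2] <- 6
  sc2 <- scenario_spec("act", list(list(variable = "physical_activity",
                                        kind = "ordinal_shift", value = 1)))
  expect_equal(apply_scenario(p, sc2)$w2$physical_activity[2], 6)
  # additive reduction floors at the scale minimum
  p$w2$alcohol_units[3] <- 1
  sc3 <- scenario_spec("alc", list(list(variable = "alcohol_units",
                                        kind = "additive", value = -2)))
  expect_equal(apply_scenario(p, sc3)$w2$alcohol_units[3], 0)
  # zero-magnitude multiplicative change is the identity
  sc0 <- scenario_spec("nil", list(list(variable = "weight_lbs",
                                        kind = "multiplicative", value = 0)))
  expect_identical(apply_scenario(p, sc0)$w2, p$w2)
  # non-modifiable variables are rejected
  scbad <- scenario_spec("bad", list(list(variable = "age",
                                          kind = "additive", value = -5)))
  expect_error(apply_scenario(p, scbad), "non-modifiable")
})

twin_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- tiny_panel(n = 700, seed = 17)
      cache <<- build_twin(p, seed = 17, nrounds = 60,
                           models = c("logistic", "gradient_boosted_trees"))
    }
    cache
  }
})

test_that("a placebo scenario changes nothing, exactly", {
  tw <- twin_fixture()
  placebo <- scenario_spec("placebo",
                           list(list(variable = "weight_lbs",
                                     kind = "multiplicative", value = 0)),
                           propagate = list(list(from = "weight_lbs",
                                                 to = "bmi",
                                                 rule = "same_relative")))
  r <- simulate_scenario(tw, placebo)
  expect_identical(max(abs(r$risk_delta)), 0)
  expect_identical(r$baseline$state_fractions, r$perturbed$state_fractions)
  expect_identical(r$baseline$predicted_cases, r$perturbed$predicted_cases)
  expect_identical(r$baseline$mean_risk, r$perturbed$mean_risk)
  expect_equal(r$n_state_changed, 0)
  expect_equal(r$n_risk_reduced, 0)
  # conservation and probability closure
  expect_equal(r$n, nrow(tw$panel$w2))
  expect_equal(sum(r$baseline$state_fractions), 1, tolerance = 1e-9)
})

test_that("improving the dominant causal exposure lowers mean predicted risk", {
  tw <- twin_fixture()
  sc <- read_scenario(system.file("extdata", "scenario_weight10.json",
                                  package = "twinforge"))
  r <- simulate_scenario(tw, sc)
  expect_lt(r$perturbed$mean_risk, r$baseline$mean_risk)
  expect_gt(r$n_risk_reduced, r$n / 2)
  # simulate() generic routes to the same deterministic engine
  r2 <- simulate(tw, scenario = sc)
  expect_equal(r2$perturbed$mean_risk, r$perturbed$mean_risk)
})

test_that("monotonicity sweeps are non-increasing on the monotone generator", {
  tw <- twin_fixture()
  ms <- monotonicity_sweep(tw, magnitudes = c(0.05, 0.10, 0.15))
  expect_true(ms$monotone_nonincreasing)
  # magnitude 0 reproduces the baseline mean risk
  m0 <- monotonicity_sweep(tw, magnitudes = 0)
  base <- simulate_scenario(tw, scenario_spec("p0", list(
    list(variable = "weight_lbs", kind = "multiplicative", value = 0))))
  expect_equal(m0$sweep$mean_risk[1], base$baseline$mean_risk)
  # duplicated magnitudes give identical values (determinism)
  md <- monotonicity_sweep(tw, magnitudes = c(0.1, 0.1))
  expect_equal(md$sweep$mean_risk[1], md$sweep$mean_risk[2])
  expect_error(monotonicity_sweep(tw, magnitudes = numeric(0)), "non-empty")
})

test_that("high-risk membership is stable across K on clumped risks", {
  r <- three_clump_risks(1200, seed = 20)
  st <- stability_analysis(r, K_range = 3:5, seed = 1)
  expect_equal(dim(st$jaccard), c(3, 3))
  expect_equal(unname(diag(st$jaccard)), rep(1, 3))
  expect_true(all(st$jaccard >= 0.9))
  # K_range = 3 alone: 1x1 matrix of self-overlap
  st3 <- stability_analysis(r, K_range = 3, seed = 1)
  expect_equal(unname(st3$jaccard[1, 1]), 1)
  expect_error(stability_analysis(r, K_range = c(1, 3)), ">= 2")
  # ids govern the membership sets
  st_ids <- stability_analysis(r, K_range = 3:4, ids = paste0("id", seq_along(r)))
  expect_true(all(grepl("^id", st_ids$high_sets[["3"]])))
})

test_that("twin accessors expose risks and states consistently", {
  tw <- twin_fixture()
  expect_equal(length(predict(tw, "risk_w2")), nrow(tw$panel$w2))
  expect_identical(predict(tw, "state_w2"),
                   assign_states(tw$risk_w2, tw$states))
  risk <- predict(tw, "outcome")
  expect_true(all(risk >= 0 & risk <= 1))
  expect_output(print(tw), "Digital twin")
  expect_output(summary(tw), "state occupancy")
})
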