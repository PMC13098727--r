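test_that("prompts assemble deterministically with metadata and ontology context", {
  idx <- build_index(load_ontology(write_ontology_fixture()), hash_embedder())
  v <- variable_metadata("bmi", "Body mass index", "biological", "continuous")
  ctx <- format_context(retrieve_concepts(v, idx, k = 2, threshold = -1))
  p1 <- build_prompt(v, ctx)
  expect_identical(p1, build_prompt(v, ctx))
  expect_match(p1, "Body mass index", fixed = TRUE)
  expect_match(p1, "→", fixed = TRUE)       # rendered triple text
  expect_match(p1, "relevance_score", fixed = TRUE)
})

test_that("the agent accepts a valid first response without requery", {
  v <- variable_metadata("sleep", "Falling or staying asleep frequency",
                         "psychosocial", "continuous")
  b <- stub_backend_scripted(
    '{"classification":"Indirect","relevance_score":0.6,"reasoning":"Sleep disturbance is associated with metabolic dysregulation."}')
  d <- classify_variable(v, NULL, b)
  expect_s3_class(d, "relevance_decision")
  expect_equal(d$relevance_score, 0.6)
  expect_equal(d$classification, "Indirect")
  expect_equal(d$requery_count, 0L)
  expect_false(d$excluded)
})

test_that("a malformed response triggers exactly one requery, then succeeds", {
  v <- variable_metadata("x", "x lab", "biological", "continuous")
  b <- stub_backend_scripted(c(
    "this is not JSON at all",
    '{"classification":"Direct","relevance_score":0.8,"reasoning":"ok"}'))
  d <- classify_variable(v, NULL, b)
  expect_equal(d$requery_count, 1L)
  expect_equal(d$relevance_score, 0.8)
  expect_false(d$excluded)
})

test_that("twice-low scores and twice-invalid responses are excluded", {
  v <- variable_metadata("x", "x lab", "administrative", "continuous")
  low <- constant_backend(0.1)
  d <- classify_variable(v, NULL, low)
  expect_true(d$excluded)
  expect_equal(d$requery_count, 1L)
  expect_equal(d$relevance_score, 0.1)
  bad <- stub_backend_scripted("still not json")
  d2 <- classify_variable(v, NULL, bad)
  expect_true(d2$excluded)
  expect_true(is.na(d2$relevance_score))
})

test_that("selection is bounded, ranked, truncated, and fully logged", {
  rows <- lapply(seq_len(300), function(i) {
    variable_metadata(sprintf("v%03d", i), sprintf("variable %03d", i),
                      "biological", "continuous")
  })
  catalog <- do.call(variable_catalog, rows)
  # deterministic per-variable scores, all above the exclusion threshold
  b <- stub_backend_keyword(function(name) {
    i <- as.integer(sub("v", "", name))
    s <- 0.3 + 0.6 * ((i * 37) %% 100) / 100
    list(relevance_score = s,
         classification = if (s >= 0.7) "Direct" else "Indirect",
         reasoning = "scripted")
  })
  r <- select_features(catalog, NULL, b, top_k = 200, batch_size = 40)
  expect_equal(nrow(r), 200)
  expect_true(all(r$score >= 0 & r$score <= 1))
  expect_false(is.unsorted(rev(r$score)))
  # bounded invocations: at most 2 per variable, and log is complete
  expect_lte(attr(r, "n_invocations"), 2 * nrow(catalog))
  expect_equal(attr(r, "n_invocations"), length(attr(r, "log")))
  # small catalog: truncation is a no-op
  r2 <- select_features(catalog[1:50, ], NULL, b, top_k = 200)
  expect_equal(nrow(r2), 50)
})

test_that("score ties preserve catalog order", {
  catalog <- variable_catalog(
    variable_metadata("alpha", "alpha", "biological", "continuous"),
    variable_metadata("beta", "beta", "biological", "continuous"),
    variable_metadata("gamma", "gamma", "biological", "continuous"))
  b <- stub_backend_keyword(function(name) {
    list(relevance_score = if (name == "gamma") 0.9 else 0.7,
         classification = if (name == "gamma") "Direct" else "Direct",
         reasoning = "tie")
  })
  r <- select_features(catalog, NULL, b, top_k = 3)
  expect_identical(r$variable, c("gamma", "alpha", "beta"))
})

test_that("ranking is a permutation-truncation of the non-excluded decisions", {
  catalog <- default_cohort_catalog(3)
  b <- stub_backend_domain(catalog)
  r <- select_features(catalog, NULL, b, top_k = 10)
  dec <- attr(r, "decisions")
  kept <- vapply(dec[!vapply(dec, `[[`, logical(1), "excluded")],
                 `[[`, character(1), "variable")
  expect_true(all(r$variable %in% kept))
  expect_false(anyDuplicated(r$variable) > 0)
  # administrative variables were excluded by the domain-aware stub
  admin <- catalog$name[catalog$domain == "administrative"]
  expect_false(any(admin %in% r$variable))
})

test_that("baseline selectors rank a perfect feature first and are deterministic", {
  set.seed(10)
  n <- 600
  X <- cbind(oracle = rep(0, n), noise1 = rnorm(n), noise2 = rnorm(n))
  y <- rbinom(n, 1, 0.4)
  X[, "oracle"] <- y               # feature equal to the outcome
  for (m in c("lasso", "mutual_information")) {
    r <- baseline_select(X, y, method = m, k = 3)
    expect_equal(r$variable[1], "oracle")
  }
  r1 <- baseline_select(X, y, "lasso", k = 3, seed = 42)
  r2 <- baseline_select(X, y, "lasso", k = 3, seed = 42)
  expect_identical(r1$variable, r2$variable)
  expect_identical(r1$score, r2$score)
  expect_warning(baseline_select(X, y, "lasso", k = 10), "exceeds")
})

test_that("mutual information of pure noise vanishes at large n", {
  set.seed(11)
  n <- 20000
  x <- rnorm(n)
  y <- rbinom(n, 1, 0.15)
  expect_lt(mutual_information_binned(x, y), 0.01)
})

test_that("semantic audit counts categories and rejects unknown variables", {
  catalog <- small_catalog()
  r <- structure(data.frame(variable = c("bmi", "activity", "interviewer_id",
                                         "rx_checklist"),
                            score = c(0.9, 0.8, 0.6, 0.5)),
                 class = c("feature_ranking", "data.frame"),
                 selection_method = "agent", k = 4)
  a <- semantic_audit(r, catalog)
  expect_equal(unname(a$counts["noise_administrative"]), 1L)
  expect_equal(unname(a$counts["proxy_downstream"]), 1L)
  expect_equal(unname(a$counts["target_relevant"]), 2L)
  expect_equal(sum(a$counts), nrow(r))
  # empty ranking -> all zero
  r0 <- r[0, , drop = FALSE]
  expect_equal(sum(semantic_audit(r0, catalog)$counts), 0L)
  # unknown variable is named in the error
  r$variable[1] <- "ghost"
  expect_error(semantic_audit(r, catalog), "ghost")
})

test_that("agent with domain tags admits fewer noise features than lasso under confounding", {
  # sampling artifact: an administrative variable correlated with the outcome
  set.seed(12)
  n <- 800
  catalog <- variable_catalog(
    variable_metadata("bmi", "Body mass index", "biological", "continuous",
                      modifiable = TRUE),
    variable_metadata("activity", "Physical activity", "behavioral",
                      "continuous", modifiable = TRUE),
    variable_metadata("batch_code", "Processing batch code", "administrative",
                      "continuous"))
  bmi <- rnorm(n); act <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.8 * bmi - 0.5 * act))
  batch <- y * 2 + rnorm(n)        # artifactually tied to the outcome
  X <- cbind(bmi = bmi, activity = act, batch_code = batch)
  lasso <- baseline_select(X, y, "lasso", k = 2)
  agent <- select_features(catalog, NULL, stub_backend_domain(catalog),
                           top_k = 2)
  audit <- semantic_audit(list(lasso = lasso, agent = agent), catalog)
  n_lasso <- audit$noise_administrative[audit$method == "lasso"]
  n_agent <- audit$noise_administrative[audit$method == "agent"]
  expect_gt(n_lasso, n_agent)
})

test_that("stub backends recover all signal variables at sufficient k", {
  spec <- cohort_spec(n_participants = 100, seed = 3)
  catalog <- spec$catalog
  signal <- names(spec$signal_coefficients)
  b <- stub_backend_keyword(function(name) {
    s <- if (name %in% signal) 0.9 else 0.1
    list(relevance_score = s,
         classification = if (s >= 0.7) "Direct" else "Unrelated",
         reasoning = "oracle stub")
  })
  r <- select_features(catalog, NULL, b, top_k = length(signal))
  expect_setequal(r$variable, signal)
})
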