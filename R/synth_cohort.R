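#' Default variable catalog for the synthetic cohort
#'
#' Variables and marginals are anchored to published descriptive statistics
#' of a midlife US panel study: baseline age 56.0 (SD 12.4) years, BMI 27.9
#' (SD 5.7) kg/m2, hypertension prevalence 30.3%, light activity 2.0 (1.5)
#' h/wk, depression score 0.6 (1.7), education 7.3 (2.5) on the study's
#' category scale, and log household income centered on a $57,500 median.
#' Physical activity lives on the study's 1-6 ordinal scale. Administrative
#' variables (interviewer id, data-collection site, plus `n_noise_vars`
#' numeric noise columns) are generated independent of the outcome and serve
#' as the "noise" class of the semantic audit.
#'
#' @param n_noise_vars Number of extra administrative noise columns.
#' @return A [variable_catalog()].
#' @export
default_cohort_catalog <- function(n_noise_vars = 5) {
  rows <- list(
    variable_metadata("age", "Age in years at baseline", "biological", "continuous"),
    variable_metadata("height_m", "Standing height (meters)", "biological", "continuous"),
    variable_metadata("bmi", "Body Mass Index - Metric", "biological", "continuous",
                      scale_min = 12, modifiable = TRUE),
    variable_metadata("weight_lbs", "Current weight (pounds)", "biological", "continuous",
                      scale_min = 60, modifiable = TRUE),
    variable_metadata("hypertension", "Hypertension ever diagnosed (12 mo)",
                      "biological", "binary"),
    variable_metadata("waist_hip_ratio", "Waist-to-hip ratio", "biological",
                      "continuous", scale_min = 0.5),
    variable_metadata("physical_activity", "Frequency of vigorous physical activity (1-6 scale)",
                      "behavioral", "ordinal", scale_min = 1, scale_max = 6,
                      modifiable = TRUE),
    variable_metadata("smoker", "Currently smokes cigarettes", "behavioral",
                      "binary", modifiable = TRUE),
    variable_metadata("alcohol_units", "Alcoholic drinks per week", "behavioral",
                      "continuous", scale_min = 0, modifiable = TRUE),
    variable_metadata("light_activity", "Light physical activity (h/wk)",
                      "behavioral", "continuous", scale_min = 0, modifiable = TRUE),
    variable_metadata("depression_score", "Depressive symptom score", "psychosocial",
                      "continuous", scale_min = 0, modifiable = TRUE),
    variable_metadata("anxiety_score", "Anxiety symptom score", "psychosocial",
                      "continuous", scale_min = 0, modifiable = TRUE),
    variable_metadata("education_yrs", "Educational attainment (category scale)",
                      "socioeconomic", "continuous"),
    variable_metadata("income_log", "Log household income", "socioeconomic",
                      "continuous"),
    variable_metadata("diabetes_medication", "Prescription medicine checklist: antidiabetic agents",
                      "biological", "binary", proxy = TRUE),
    variable_metadata("interviewer_id", "Interviewer ID", "administrative", "categorical"),
    variable_metadata("site", "Data Collection Site", "administrative", "categorical")
  )
  if (n_noise_vars > 0) {
    for (i in seq_len(n_noise_vars)) {
      rows[[length(rows) + 1L]] <- variable_metadata(
        sprintf("admin_noise_%02d", i),
        sprintf("Administrative processing field %02d", i),
        "administrative", "continuous")
    }
  }
  do.call(variable_catalog, rows)
}

#' Default ground-truth log-odds weights of the synthetic outcome model
#'
#' Positive weights on age, adiposity, hypertension, smoking and distress;
#' protective weights on physical activity, income and education. Together
#' with the incidence-calibrated intercept these define the logistic model
#' from which wave-3 disease onset is drawn.
#'
#' @return Named numeric vector of log-odds per unit of the natural scale.
#' @export
default_signal_coefficients <- function() {
  c(age = 0.045, bmi = 0.14, hypertension = 0.8,
    physical_activity = -0.30, smoker = 0.45,
    depression_score = 0.15, anxiety_score = 0.10,
    income_log = -0.30, education_yrs = -0.05)
}

#' Specify a synthetic two-wave cohort
#'
#' @param n_participants Cohort size (default 4174, the paired-panel size the
#'   generator emulates).
#' @param seed Integer seed; the whole panel is a deterministic function of it.
#' @param signal_coefficients Named log-odds weights of the true outcome
#'   model; every name must be a generated variable.
#' @param intercept Logistic intercept, or `NULL` to calibrate it so the mean
#'   true risk equals `target_incidence`.
#' @param target_incidence Target wave-3 incidence in (0, 1); default 0.147.
#' @param n_noise_vars Number of administrative noise variables.
#' @param drift Named per-variable mean shift from wave 2 to wave 3.
#' @param missingness Named list: each element
#'   `list(fraction =, mechanism = "MCAR")` or
#'   `list(fraction =, mechanism = "MAR", covariate = "age")`.
#' @param attrition_fraction Fraction of participants whose wave-3 record is
#'   dropped before pairing.
#' @param catalog Variable catalog; defaults to [default_cohort_catalog()].
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_participants = 4174, seed = 42,
                        signal_coefficients = default_signal_coefficients(),
                        intercept = NULL, target_incidence = 0.147,
                        n_noise_vars = 5,
                        drift = c(age = 9, bmi = 0.3, education_yrs = 0.3,
                                  income_log = 0.18),
                        missingness = list(),
                        attrition_fraction = 0,
                        catalog = default_cohort_catalog(n_noise_vars)) {
  stopifnot(n_participants >= 1, is.numeric(seed))
  if (!is.null(target_incidence) &&
      (target_incidence <= 0 || target_incidence >= 1)) {
    stop("target_incidence must lie strictly inside (0, 1)")
  }
  unknown <- setdiff(names(signal_coefficients), catalog$name)
  if (length(unknown)) {
    stop("signal_coefficients name variables not in the catalog: ",
         paste(unknown, collapse = ", "))
  }
  if (attrition_fraction < 0 || attrition_fraction >= 1) {
    stop("attrition_fraction must lie in [0, 1)")
  }
  for (v in names(missingness)) {
    m <- missingness[[v]]
    if (m$fraction < 0 || m$fraction >= 1) stop("missingness fraction for '", v,
                                                "' must lie in [0, 1)")
    if (identical(m$mechanism, "MAR") && is.null(m$covariate)) {
      stop("MAR missingness for '", v, "' requires a named covariate")
    }
  }
  structure(list(n_participants = as.integer(n_participants),
                 seed = as.integer(seed),
                 signal_coefficients = signal_coefficients,
                 intercept = intercept,
                 target_incidence = target_incidence,
                 n_noise_vars = as.integer(n_noise_vars),
                 drift = drift, missingness = missingness,
                 attrition_fraction = attrition_fraction,
                 catalog = catalog),
            class = "cohort_spec")
}

## Draw the wave-2 cross-section. RNG call order is fixed so panels are
## reproducible bit-for-bit from the seed.
draw_wave2 <- function(spec) {
  n <- spec$n_participants
  age <- rnorm(n, 56.0, 12.4)
  height_m <- rnorm(n, 1.70, 0.10)
  bmi <- pmax(rnorm(n, 27.9, 5.7), 15)
  weight_lbs <- bmi * height_m^2 * 2.20462
  hypertension <- rbinom(n, 1, plogis(qlogis(0.303) + 0.08 * (bmi - 27.9)))
  waist_hip_ratio <- pmax(0.75 + 0.005 * (bmi - 27.9) + rnorm(n, 0, 0.06), 0.6)
  physical_activity <- pmin(pmax(round(rnorm(n, 3.5, 1.2)), 1), 6)
  smoker <- rbinom(n, 1, 0.25)
  alcohol_units <- pmax(rnorm(n, 4, 3), 0)
  light_activity <- pmax(rnorm(n, 2.0, 1.5), 0)
  depression_score <- pmax(rnorm(n, 0.6, 1.7), 0)
  anxiety_score <- pmax(rnorm(n, 1.5, 1.2), 0)
  education_yrs <- rnorm(n, 7.3, 2.5)
  income_log <- rnorm(n, log(57500), 0.8)
  ## downstream proxy: strongly tied to latent risk drivers, not modifiable
  diabetes_medication <- rbinom(n, 1, plogis(-4 + 0.12 * (bmi - 27.9) +
                                               1.0 * hypertension))
  interviewer_id <- sample(sprintf("INT%02d", 1:10), n, replace = TRUE)
  site <- sample(sprintf("SITE%d", 1:5), n, replace = TRUE)
  df <- data.frame(participant_id = seq_len(n), age = age, height_m = height_m,
                   bmi = bmi, weight_lbs = weight_lbs,
                   hypertension = hypertension,
                   waist_hip_ratio = waist_hip_ratio,
                   physical_activity = physical_activity, smoker = smoker,
                   alcohol_units = alcohol_units,
                   light_activity = light_activity,
                   depression_score = depression_score,
                   anxiety_score = anxiety_score,
                   education_yrs = education_yrs, income_log = income_log,
                   diabetes_medication = diabetes_medication,
                   interviewer_id = interviewer_id, site = site,
                   stringsAsFactors = FALSE)
  if (spec$n_noise_vars > 0) {
    for (i in seq_len(spec$n_noise_vars)) {
      df[[sprintf("admin_noise_%02d", i)]] <- rnorm(n)
    }
  }
  df
}

## Wave 3 = wave 2 + configured drift + Gaussian innovation (no explicit
## dynamics are modeled: paired records only).
draw_wave3 <- function(w2, spec) {
  w3 <- w2
  drift <- spec$drift
  inno <- c(bmi = 1.7, waist_hip_ratio = 0.03, alcohol_units = 1.2,
            light_activity = 0.6, depression_score = 0.6, anxiety_score = 0.5,
            education_yrs = 0.3, income_log = 0.25)
  for (v in c("bmi", "waist_hip_ratio", "alcohol_units", "light_activity",
              "depression_score", "anxiety_score", "education_yrs",
              "income_log")) {
    d <- if (v %in% names(drift)) drift[[v]] else 0
    w3[[v]] <- w2[[v]] + d + rnorm(nrow(w2), 0, inno[[v]])
  }
  if ("age" %in% names(drift)) w3$age <- w2$age + drift[["age"]]
  lo <- c(bmi = 15, waist_hip_ratio = 0.6, alcohol_units = 0,
          light_activity = 0, depression_score = 0, anxiety_score = 0)
  for (v in names(lo)) w3[[v]] <- pmax(w3[[v]], lo[[v]])
  w3$weight_lbs <- w3$bmi * w3$height_m^2 * 2.20462
  w3$physical_activity <- pmin(pmax(round(
    w2$physical_activity + rnorm(nrow(w2), 0, 0.7)), 1), 6)
  quit <- rbinom(nrow(w2), 1, 0.15)
  start <- rbinom(nrow(w2), 1, 0.02)
  w3$smoker <- ifelse(w2$smoker == 1, 1 - quit, start)
  onset <- rbinom(nrow(w2), 1, 0.123)
  w3$hypertension <- pmax(w2$hypertension, onset)
  w3
}

#' Generate a reproducible two-wave synthetic cohort
#'
#' Draws a baseline cross-section with the catalog's marginals, evolves it to
#' the follow-up wave (configured drift plus Gaussian innovation), draws the
#' binary follow-up outcome from the logistic ground-truth model on baseline
#' values, applies attrition and item missingness, and pairs the waves. The
#' intercept is calibrated by one-dimensional root finding so the mean true
#' risk equals the target incidence.
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort_panel`: list with wide data frames `w2` and `w3` (one row
#'   per participant), `outcome_w3` (named 0/1 vector), `catalog`, and
#'   `provenance` (the spec, with the calibrated intercept filled in).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  w2 <- draw_wave2(spec)
  w3 <- draw_wave3(w2, spec)
  for (v in spec$catalog$name[spec$catalog$dtype != "categorical"]) {
    w2[[v]] <- as.numeric(w2[[v]])
    w3[[v]] <- as.numeric(w3[[v]])
  }
  lp <- linear_predictor(w2, spec$signal_coefficients)
  intercept <- spec$intercept
  if (is.null(intercept)) {
    target <- spec$target_incidence
    f <- function(b0) mean(plogis(b0 + lp)) - target
    intercept <- uniroot(f, c(-40, 40), tol = 1e-10)$root
  }
  risk <- plogis(intercept + lp)
  outcome <- as.integer(rbinom(length(risk), 1, risk))
  names(outcome) <- w2$participant_id
  spec$intercept <- intercept
  panel <- structure(list(w2 = w2, w3 = w3, outcome_w3 = outcome,
                          catalog = spec$catalog, provenance = spec),
                     class = "cohort_panel")
  if (length(spec$missingness) > 0 || spec$attrition_fraction > 0) {
    panel <- inject_missingness(panel, spec)
  }
  panel
}

#' @keywords internal
linear_predictor <- function(w2, coefs) {
  lp <- numeric(nrow(w2))
  for (v in names(coefs)) lp <- lp + coefs[[v]] * w2[[v]]
  lp
}

#' Ground-truth outcome probabilities of a generated panel
#'
#' The oracle used by parameter-recovery and Bayes-AUC tests:
#' `plogis(intercept + sum(coef * wave-2 value))` per participant.
#'
#' @param panel A `cohort_panel` produced by [generate_cohort()].
#' @param spec The spec it was generated from (defaults to the panel's
#'   provenance).
#' @return Numeric probability vector named by participant id.
#' @export
true_risk <- function(panel, spec = panel$provenance) {
  stopifnot(inherits(panel, "cohort_panel"))
  if (!inherits(spec, "cohort_spec")) {
    stop("true_risk requires a generated panel; provenance is 'external'")
  }
  if (is.null(spec$intercept)) stop("spec has no calibrated intercept")
  lp <- linear_predictor(panel$w2, spec$signal_coefficients)
  r <- plogis(spec$intercept + lp)
  names(r) <- panel$w2$participant_id
  r
}

#' Inject item missingness and wave-level attrition
#'
#' MCAR missingness blanks a Bernoulli(`fraction`) subset of a variable's
#' values. MAR missingness conditions on the named covariate: records above
#' its median go missing with probability `2 * fraction`, records below never
#' do, preserving the marginal rate. Attrition removes whole wave-3 records;
#' the panel is then re-paired so every remaining participant has both waves.
#'
#' @param panel A `cohort_panel`.
#' @param spec A [cohort_spec()] carrying `missingness` and
#'   `attrition_fraction`.
#' @return The panel with `NA` markers and attrition applied.
#' @export
inject_missingness <- function(panel, spec) {
  stopifnot(inherits(panel, "cohort_panel"))
  if (spec$attrition_fraction > 0) {
    n <- nrow(panel$w3)
    drop_n <- floor(spec$attrition_fraction * n)
    dropped <- sample(panel$w3$participant_id, drop_n)
    keep <- !(panel$w3$participant_id %in% dropped)
    panel$w3 <- panel$w3[keep, , drop = FALSE]
    keep2 <- panel$w2$participant_id %in% panel$w3$participant_id
    panel$w2 <- panel$w2[keep2, , drop = FALSE]
    panel$outcome_w3 <- panel$outcome_w3[as.character(panel$w2$participant_id)]
  }
  for (v in names(spec$missingness)) {
    m <- spec$missingness[[v]]
    if (!v %in% panel$catalog$name) stop("missingness names unknown variable '", v, "'")
    for (wv in c("w2", "w3")) {
      x <- panel[[wv]][[v]]
      if (is.null(x)) next
      if (identical(m$mechanism, "MAR")) {
        cov <- m$covariate
        if (!cov %in% names(panel[[wv]])) {
          stop("MAR covariate '", cov, "' not in catalog/panel")
        }
        hi <- panel[[wv]][[cov]] > median(panel[[wv]][[cov]], na.rm = TRUE)
        p <- ifelse(hi, pmin(2 * m$fraction, 1), 0)
      } else {
        p <- rep(m$fraction, length(x))
      }
      blank <- runif(length(x)) < p
      x[blank] <- NA
      panel[[wv]][[v]] <- x
    }
  }
  panel
}

#' @export
print.cohort_panel <- function(x, ...) {
  cat("Two-wave cohort panel\n")
  cat(sprintf("  participants: %d (paired)\n", nrow(x$w2)))
  cat(sprintf("  variables:    %d (%s)\n", nrow(x$catalog),
              paste(sprintf("%d %s", table(x$catalog$domain)[unique(x$catalog$domain)],
                            unique(x$catalog$domain)), collapse = ", ")))
  cat(sprintf("  outcome_w3 incidence: %.3f\n", mean(x$outcome_w3)))
  prov <- if (inherits(x$provenance, "cohort_spec")) {
    sprintf("synthetic (seed %d)", x$provenance$seed)
  } else "external"
  cat("  provenance:  ", prov, "\n")
  invisible(x)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "", formatC(x, digits = 17, format = "g"))
}

#' Write / read a cohort panel as plain text
#'
#' The panel is serialized as a long CSV (one row per participant per wave,
#' `participant_id` and `wave` columns, `outcome_w3` populated on W3 rows)
#' plus a JSON data dictionary holding the variable catalog and provenance.
#' Numeric values are written with 17 significant digits so the round trip is
#' exact; `NA` missing markers survive as empty fields.
#'
#' @param panel A `cohort_panel`.
#' @param path CSV path for the long table.
#' @param dict_path JSON path for the data dictionary.
#' @return `write_panel` invisibly returns `path`; `read_panel` returns the
#'   reconstructed `cohort_panel`.
#' @export
write_panel <- function(panel, path, dict_path = sub("\\.csv$", ".dict.json", path)) {
  stopifnot(inherits(panel, "cohort_panel"))
  vars <- panel$catalog$name
  long <- rbind(
    data.frame(participant_id = panel$w2$participant_id, wave = "W2",
               panel$w2[, vars, drop = FALSE], outcome_w3 = NA,
               check.names = FALSE, stringsAsFactors = FALSE),
    data.frame(participant_id = panel$w3$participant_id, wave = "W3",
               panel$w3[, vars, drop = FALSE],
               outcome_w3 = unname(panel$outcome_w3[as.character(panel$w3$participant_id)]),
               check.names = FALSE, stringsAsFactors = FALSE))
  out <- long
  num <- vapply(out, is.numeric, logical(1))
  for (j in which(num)) out[[j]] <- fmt_num(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  prov <- panel$provenance
  dict <- list(catalog = panel$catalog,
               provenance = if (inherits(prov, "cohort_spec")) {
                 sp <- prov[setdiff(names(prov), "catalog")]
                 ## named vectors serialize as JSON objects, keeping names
                 sp$signal_coefficients <- as.list(sp$signal_coefficients)
                 sp$drift <- as.list(sp$drift)
                 list(kind = "synthetic", spec = sp)
               } else list(kind = "external"))
  jsonlite::write_json(dict, dict_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path, dict_path = sub("\\.csv$", ".dict.json", path)) {
  dict <- jsonlite::read_json(dict_path, simplifyVector = TRUE)
  catalog <- validate_catalog(as.data.frame(dict$catalog, stringsAsFactors = FALSE))
  long <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                          check.names = FALSE)
  missing_cols <- setdiff(catalog$name, names(long))
  if (length(missing_cols)) {
    stop("panel table is missing dictionary column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(long), c("participant_id", "wave", "outcome_w3", catalog$name))
  if (length(extra)) {
    stop("panel table has column(s) absent from the dictionary: ",
         paste(extra, collapse = ", "))
  }
  for (i in seq_len(nrow(catalog))) {
    v <- catalog$name[i]
    if (catalog$dtype[i] != "categorical") long[[v]] <- as.numeric(long[[v]])
  }
  w2 <- long[long$wave == "W2", c("participant_id", catalog$name), drop = FALSE]
  w3 <- long[long$wave == "W3", c("participant_id", catalog$name), drop = FALSE]
  rownames(w2) <- rownames(w3) <- NULL
  oc <- long[long$wave == "W3", c("participant_id", "outcome_w3")]
  outcome <- as.integer(oc$outcome_w3)
  names(outcome) <- oc$participant_id
  prov <- if (identical(dict$provenance$kind, "synthetic")) {
    sp <- dict$provenance$spec
    sp$signal_coefficients <- unlist(sp$signal_coefficients)
    sp$drift <- unlist(sp$drift)
    structure(c(sp, list(catalog = catalog)), class = "cohort_spec")
  } else "external"
  structure(list(w2 = w2, w3 = w3, outcome_w3 = outcome,
                 catalog = catalog, provenance = prov),
            class = "cohort_panel")
}
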