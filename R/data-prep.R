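#' Harmonize raw service fields into the 12 binary RMNCH indicators
#'
#' Applies the indicator definitions used throughout the analysis: the
#' antenatal-care indicator follows the WHO guideline change, requiring at
#' least four visits for surveys before 2017 and at least eight from 2017
#' onward; tetanus protection requires at least two toxoid doses; DPT and
#' polio require three doses each. The remaining flags (facility delivery,
#' skilled attendance, postnatal checks within two days, BCG, measles,
#' age-appropriate breastfeeding, modern family planning) pass through
#' unchanged — breastfeeding in particular is accepted as a pre-coded binary.
#' Missing inputs propagate to missing indicators. Records with an unusable
#' survey year are retained with ANC set to missing and reported in the
#' `problems` attribute.
#'
#' @param raw Tibble with per-record columns `country_id`, `survey_year`,
#'   `weight`, the count fields `anc_visits`, `tetanus_doses`, `dpt_doses`,
#'   `polio_doses`, the flag fields `facility_delivery`, `skilled_attendant`,
#'   `pnc_mother_2d`, `pnc_newborn_2d`, `modern_fp`, `bcg`, `measles`,
#'   `age_appropriate_bf`, plus any covariate columns (passed through).
#' @return Tibble with the 12 indicator columns named as in
#'   [rmnch_indicators()], identifier/weight/covariate columns preserved, and
#'   a `problems` attribute tibble (`record`, `issue`).
#' @export
harmonize_indicators <- function(raw) {
  needed <- c("country_id", "survey_year", "anc_visits", "tetanus_doses",
              "facility_delivery", "skilled_attendant", "pnc_mother_2d",
              "pnc_newborn_2d", "modern_fp", "bcg", "dpt_doses", "polio_doses",
              "measles", "age_appropriate_bf")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    abort(paste0("Missing raw columns: ", paste(missing_cols, collapse = ", ")))
  yr <- suppressWarnings(as.integer(raw$survey_year))
  bad_year <- !is.na(raw$survey_year) & (is.na(yr) | yr < 1000 | yr > 9999)
  yr[bad_year] <- NA_integer_
  problems <- tibble(record = which(bad_year | is.na(raw$survey_year)),
                     issue = "unusable survey_year; ANC set to missing")
  anc_thresh <- ifelse(yr < 2017, 4L, 8L)
  as_flag <- function(x) {
    x <- as.integer(x)
    if (any(!x %in% c(0L, 1L, NA))) abort("Flags must be 0, 1 or missing.")
    x
  }
  out <- dplyr::mutate(
    raw,
    anc = as.integer(.data$anc_visits >= anc_thresh),
    tetanus = as.integer(.data$tetanus_doses >= 2),
    facility_delivery = as_flag(.data$facility_delivery),
    skilled_attendant = as_flag(.data$skilled_attendant),
    pnc_mother = as_flag(.data$pnc_mother_2d),
    pnc_newborn = as_flag(.data$pnc_newborn_2d),
    bcg = as_flag(.data$bcg),
    dpt = as.integer(.data$dpt_doses >= 3),
    polio = as.integer(.data$polio_doses >= 3),
    measles = as_flag(.data$measles),
    breastfeeding = as_flag(.data$age_appropriate_bf),
    family_planning = as_flag(.data$modern_fp))
  out <- dplyr::select(out, -dplyr::all_of(c("anc_visits", "tetanus_doses",
                                             "dpt_doses", "polio_doses",
                                             "pnc_mother_2d", "pnc_newborn_2d",
                                             "modern_fp", "age_appropriate_bf")))
  out <- dplyr::relocate(out, dplyr::all_of(rmnch_indicators()),
                         .after = dplyr::last_col())
  attr(out, "problems") <- problems
  out
}

#' Multiple imputation of binary indicators by chained equations
#'
#' Fills missing indicator cells with the standard chained-equations sampler
#' for binary data: variables are visited in order of increasing missingness;
#' each incomplete variable is regressed (logistic) on all other variables in
#' `vars` using currently completed data, coefficients are drawn from their
#' asymptotic normal distribution, and imputations are drawn from the
#' resulting Bernoulli predictive distribution. Observed cells are never
#' changed.
#'
#' @param data Unit-record tibble.
#' @param vars Columns to impute / use as predictors (default: the canonical
#'   indicators present in `data`). All must be binary 0/1/NA.
#' @param predictors Additional complete columns used as predictors only.
#' @param cycles Chained-equation cycles per imputation (default 10).
#' @param m Number of completed datasets (default 5).
#' @param seed Integer seed.
#' @return A list of `m` completed tibbles.
#' @export
chained_impute <- function(data, vars = intersect(rmnch_indicators(), names(data)),
                           predictors = character(), cycles = 10L, m = 5L,
                           seed = 1L) {
  if (!length(vars)) abort("No variables to impute.")
  for (v in vars) {
    if (!all(data[[v]] %in% c(0, 1, NA))) abort(sprintf("`%s` must be binary 0/1/NA.", v))
    if (all(is.na(data[[v]])))
      abort(sprintf("Variable `%s` has no observed values and cannot be imputed.", v))
  }
  n_miss <- vapply(vars, function(v) sum(is.na(data[[v]])), integer(1))
  incomplete <- names(sort(n_miss[n_miss > 0]))  # visit order: increasing missingness
  if (!length(incomplete)) return(replicate(m, data, simplify = FALSE))
  seeds <- split_seed(seed, m)
  lapply(seq_len(m), function(d) {
    set.seed(seeds[d])
    filled <- data
    for (v in incomplete) {  # initial fill from the observed marginal
      mis <- is.na(filled[[v]])
      filled[[v]][mis] <- sample(data[[v]][!is.na(data[[v]])], sum(mis), replace = TRUE)
    }
    rhs <- setdiff(c(vars, predictors), character(0))
    for (cy in seq_len(cycles)) {
      for (v in incomplete) {
        mis <- is.na(data[[v]])
        preds <- setdiff(rhs, v)
        X <- stats::model.matrix(~ ., data = filled[preds])
        fit <- suppressWarnings(glm.fit(X[!mis, , drop = FALSE], data[[v]][!mis],
                                        family = binomial()))
        beta_hat <- coef(fit)
        beta_hat[is.na(beta_hat)] <- 0  # aliased columns drop out
        # asymptotic-normal parameter draw (proper imputation); a ridge keeps
        # the information invertible under near-collinear predictors
        Xo <- X[!mis, , drop = FALSE]
        p_o <- plogis(drop(Xo %*% beta_hat))
        info <- crossprod(Xo * sqrt(pmax(p_o * (1 - p_o), 1e-8))) +
          diag(1e-4, ncol(Xo))
        L <- tryCatch(chol(solve(info)), error = function(e) NULL)
        beta_star <- if (is.null(L)) beta_hat else
          beta_hat + drop(t(L) %*% rnorm(length(beta_hat)))
        p_mis <- plogis(drop(X[mis, , drop = FALSE] %*% beta_star))
        filled[[v]][mis] <- rbinom(sum(mis), 1L, p_mis)
      }
    }
    filled
  })
}

#' @importFrom stats glm.fit
NULL

#' Weighted descriptive summaries of indicators and country shares
#'
#' Returns the descriptive tables of the analysis: per indicator, the weighted
#' number of women who received the service and its percentage of the total
#' weighted sample; per country, the weighted sample count and its percentage
#' share. Percentages are rounded to one decimal.
#'
#' @param data Unit-record tibble with indicator columns, `country_id` and an
#'   optional `weight` column (unit weights assumed otherwise).
#' @param indicators Indicator columns to summarize.
#' @param group,weight Column names.
#' @return List of tibbles `indicators` (`indicator, weighted_n, percent`) and
#'   `countries` (`country_id, weighted_n, percent`).
#' @export
weighted_summaries <- function(data, indicators = intersect(rmnch_indicators(), names(data)),
                               group = "country_id", weight = "weight") {
  if (!nrow(data)) abort("Empty dataset.")
  w <- if (weight %in% names(data)) as.numeric(data[[weight]]) else rep(1, nrow(data))
  if (any(w <= 0)) abort("Weights must be positive.")
  total <- sum(w)
  ind_tab <- purrr::map_dfr(indicators, function(v) {
    got <- !is.na(data[[v]]) & data[[v]] == 1
    tibble(indicator = v, weighted_n = sum(w[got]),
           percent = round(100 * sum(w[got]) / total, 1))
  })
  ctry_tab <- data |>
    dplyr::mutate(.w = w) |>
    dplyr::group_by(country_id = .data[[group]]) |>
    dplyr::summarise(weighted_n = sum(.data$.w), .groups = "drop") |>
    dplyr::mutate(percent = round(100 * .data$weighted_n / total, 1))
  list(indicators = ind_tab, countries = ctry_tab)
}
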