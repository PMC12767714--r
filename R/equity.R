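#' Aggregate a record-level outcome into a stratified-outcome object
#'
#' Summarizes a bounded outcome (by convention the posterior probability of
#' the optimal-utilizer class, or its MAP indicator) over the levels of an
#' equity stratifier: weighted population shares \eqn{p_g}, weighted subgroup
#' means \eqn{y_g}, and the overall mean \eqn{\mu = \sum_g p_g y_g}. For
#' ordered stratifiers supply `order` from most disadvantaged to most
#' advantaged; midpoint cumulative ranks \eqn{x_g = \sum_{g'<g} p_{g'} +
#' p_g/2} are attached. Record-level backing data are retained for
#' country-clustered resampling.
#'
#' @param data Record-level tibble.
#' @param outcome Name of the outcome column (values in `[0, 1]`).
#' @param subgroup Name of the stratifier column.
#' @param order Optional character vector of subgroup labels, disadvantaged
#'   first; its presence marks the stratifier as ordered.
#' @param country,weight Column names for the clustering id and weights.
#' @return Object of class `strat_outcome`: `groups` tibble
#'   (`subgroup, p, y, x`), `mu`, `ordered`, and the backing records.
#' @export
stratified_outcome <- function(data, outcome, subgroup, order = NULL,
                               country = "country_id", weight = "weight") {
  for (col in c(outcome, subgroup, country)) {
    if (!col %in% names(data)) abort(sprintf("Column `%s` not found.", col))
  }
  y <- as.numeric(data[[outcome]])
  if (any(is.na(y)) || any(y < 0 | y > 1)) abort("`outcome` must lie in [0, 1].")
  w <- if (weight %in% names(data)) as.numeric(data[[weight]]) else rep(1, nrow(data))
  backing <- tibble(outcome = y, subgroup = as.character(data[[subgroup]]),
                    country = data[[country]], weight = w)
  levels_g <- if (!is.null(order)) order else sort(unique(backing$subgroup))
  extra <- setdiff(unique(backing$subgroup), levels_g)
  if (length(extra))
    abort(paste0("Subgroups missing from `order`: ", paste(extra, collapse = ", ")))
  build_strat(backing, levels_g, ordered = !is.null(order))
}

build_strat <- function(backing, levels_g, ordered) {
  present <- levels_g[levels_g %in% backing$subgroup]
  agg <- backing |>
    dplyr::mutate(subgroup = factor(.data$subgroup, levels = present)) |>
    dplyr::group_by(.data$subgroup) |>
    dplyr::summarise(p = sum(.data$weight), y = weighted.mean(.data$outcome, .data$weight),
                     .groups = "drop") |>
    dplyr::mutate(p = .data$p / sum(.data$p),
                  x = cumsum(.data$p) - .data$p / 2)
  structure(list(groups = agg, mu = sum(agg$p * agg$y),
                 ordered = ordered, levels = present, backing = backing),
            class = "strat_outcome")
}

#' @exportS3Method base::print
print.strat_outcome <- function(x, ...) {
  cat(sprintf("Stratified outcome (%s), mu = %.4f\n",
              if (x$ordered) "ordered" else "unordered", x$mu))
  print(x$groups)
  invisible(x)
}

#' Simple inequality measures: absolute difference and relative ratio
#'
#' `difference` \eqn{= y_{adv} - y_{dis}}; `ratio` \eqn{= y_{adv}/y_{dis}}.
#'
#' @param s A [stratified_outcome()].
#' @param advantaged,disadvantaged Subgroup labels to compare.
#' @return Tibble `measure, estimate, type`.
#' @export
simple_measures <- function(s, advantaged, disadvantaged) {
  stopifnot(inherits(s, "strat_outcome"))
  g <- s$groups
  for (lab in c(advantaged, disadvantaged)) {
    if (!lab %in% g$subgroup) abort(sprintf("Subgroup `%s` not present.", lab))
  }
  ya <- g$y[g$subgroup == advantaged]
  yd <- g$y[g$subgroup == disadvantaged]
  if (yd == 0) abort("Disadvantaged-subgroup mean is 0; ratio undefined.")
  tibble(measure = c("difference", "ratio"),
         estimate = c(ya - yd, ya / yd),
         type = c("absolute", "relative"))
}

#' Absolute and relative concentration indices for an ordered stratifier
#'
#' With subgroups ranked disadvantaged to advantaged and midpoint cumulative
#' ranks \eqn{x_g}:
#' \deqn{RCI = \frac{2}{\mu}\sum_g p_g y_g x_g - 1, \qquad ACI = \mu \cdot RCI.}
#' Positive values concentrate the outcome among the advantaged.
#'
#' @param s An ordered [stratified_outcome()].
#' @return Tibble `measure, estimate, type` with rows `ACI`, `RCI`.
#' @export
concentration_indices <- function(s) {
  stopifnot(inherits(s, "strat_outcome"))
  if (!s$ordered) abort("Concentration indices need an ordered stratifier.")
  g <- s$groups
  rci <- 2 / s$mu * sum(g$p * g$y * g$x) - 1
  tibble(measure = c("ACI", "RCI"), estimate = c(s$mu * rci, rci),
         type = c("absolute", "relative"))
}

#' Slope and relative indices of inequality
#'
#' Regresses the subgroup means on their midpoint cumulative ranks, weighted
#' by population shares, using a logit (default, respecting the bounded
#' outcome) or identity link; predictions at the extremes of the rank scale
#' give \eqn{\nu_0} (most disadvantaged) and \eqn{\nu_1} (most advantaged),
#' with \eqn{SII = \nu_1 - \nu_0} and \eqn{RII = \nu_1/\nu_0}.
#'
#' @param s An ordered [stratified_outcome()] with >= 2 subgroups.
#' @param link `"logit"` or `"identity"`.
#' @return Tibble `measure, estimate, type` with rows `SII`, `RII`.
#' @export
sii_rii <- function(s, link = c("logit", "identity")) {
  stopifnot(inherits(s, "strat_outcome"))
  link <- match.arg(link)
  if (!s$ordered) abort("SII/RII need an ordered stratifier.")
  g <- s$groups
  if (nrow(g) < 2) abort("SII/RII need at least 2 subgroups.")
  if (link == "logit") {
    fit <- suppressWarnings(glm(y ~ x, data = g, weights = g$p,
                                family = stats::quasibinomial("logit")))
    nu <- plogis(coef(fit)[1L] + coef(fit)[2L] * c(0, 1))
  } else {
    fit <- stats::lm(y ~ x, data = g, weights = g$p)
    nu <- coef(fit)[1L] + coef(fit)[2L] * c(0, 1)
  }
  if (nu[1L] == 0) abort("Fitted value at rank 0 is 0; RII undefined.")
  tibble(measure = c("SII", "RII"),
         estimate = c(nu[2L] - nu[1L], nu[2L] / nu[1L]),
         type = c("absolute", "relative"))
}

#' Population attributable risk and fraction
#'
#' The absolute (`PAR`) and percentage (`PAF`) gain in overall coverage if
#' every subgroup attained the reference subgroup's mean: \eqn{PAR =
#' \max(y_{ref} - \mu, 0)} and \eqn{PAF = 100 \cdot PAR / \mu}. The default
#' reference is the best-performing subgroup of this favourable outcome.
#'
#' @param s A [stratified_outcome()] with `mu > 0`.
#' @param reference A subgroup label, or `"best"`.
#' @return Tibble `measure, estimate, type` with rows `PAR`, `PAF`.
#' @export
par_paf <- function(s, reference = "best") {
  stopifnot(inherits(s, "strat_outcome"))
  if (s$mu <= 0) abort("Overall mean must be positive.")
  g <- s$groups
  y_ref <- if (identical(reference, "best")) max(g$y) else {
    if (!reference %in% g$subgroup) abort(sprintf("Subgroup `%s` not present.", reference))
    g$y[g$subgroup == reference]
  }
  par <- max(y_ref - s$mu, 0)
  tibble(measure = c("PAR", "PAF"), estimate = c(par, 100 * par / s$mu),
         type = c("absolute", "relative"))
}

equity_measure_fun <- function(measure, ...) {
  args <- list(...)
  switch(measure,
    difference = ,
    ratio = function(s) simple_measures(s, args$advantaged, args$disadvantaged),
    ACI = ,
    RCI = function(s) concentration_indices(s),
    SII = ,
    RII = function(s) sii_rii(s, link = args$link %||% "logit"),
    PAR = ,
    PAF = function(s) par_paf(s, reference = args$reference %||% "best"),
    abort(sprintf("Unknown measure '%s'.", measure)))
}

#' Country-clustered bootstrap confidence interval for an equity measure
#'
#' Resamples countries with replacement `B` times, re-aggregates subgroup
#' means on each replicate, recomputes the measure, and reports the
#' percentile interval — the clustering-at-the-national-level inference used
#' throughout the inequality analysis.
#'
#' @param s A [stratified_outcome()] whose backing data span >= 2 countries.
#' @param measure One of `"difference"`, `"ratio"`, `"ACI"`, `"RCI"`,
#'   `"SII"`, `"RII"`, `"PAR"`, `"PAF"`.
#' @param B Bootstrap replicates (default 1000).
#' @param level Confidence level.
#' @param seed Integer seed.
#' @param ... Measure options: `advantaged`/`disadvantaged` labels for the
#'   simple measures, `link` for SII/RII, `reference` for PAR/PAF.
#' @return One-row tibble `measure, estimate, CI_low, CI_high, type,
#'   n_countries, B`.
#' @export
cluster_bootstrap_ci <- function(s, measure, B = 1000L, level = 0.95,
                                 seed = 1L, ...) {
  stopifnot(inherits(s, "strat_outcome"))
  countries <- unique(s$backing$country)
  if (length(countries) < 2L) abort("Cluster bootstrap needs >= 2 countries.")
  if (B == 1L) warn("B = 1 gives a degenerate interval equal to the single replicate.")
  fun <- equity_measure_fun(measure, ...)
  point <- dplyr::filter(fun(s), .data$measure == !!measure)
  by_country <- split(seq_len(nrow(s$backing)), s$backing$country)
  set.seed(as.integer(seed))
  reps <- vapply(seq_len(B), function(b) {
    draw <- sample(countries, length(countries), replace = TRUE)
    idx <- unlist(by_country[as.character(draw)], use.names = FALSE)
    sb <- build_strat(s$backing[idx, , drop = FALSE], s$levels, s$ordered)
    tryCatch(dplyr::filter(fun(sb), .data$measure == !!measure)$estimate,
             error = function(e) NA_real_)
  }, numeric(1))
  ok <- reps[is.finite(reps)]
  if (length(ok) < B) warn(sprintf("%d of %d replicates failed and were dropped.",
                                   B - length(ok), B))
  qs <- quantile(ok, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  tibble(measure = measure, estimate = point$estimate,
         CI_low = qs[1L], CI_high = qs[2L], type = point$type,
         n_countries = length(countries), B = B)
}

#' Full inequality table across equity dimensions
#'
#' Convenience wrapper producing the analysis's inequality table: for each
#' configured dimension, the applicable measures (difference/ratio for binary
#' dimensions; additionally concentration and slope indices for ordered ones;
#' PAR/PAF for all) with country-clustered bootstrap CIs.
#'
#' @param data Record-level tibble with the outcome column.
#' @param outcome Outcome column name.
#' @param dimensions Named list; each element is a list with `subgroup`
#'   (column name), optional `order` (disadvantaged to advantaged; marks the
#'   dimension ordered), and optional `advantaged`/`disadvantaged` labels
#'   (default: last/first of `order` or of the sorted labels).
#' @param B,level,seed Bootstrap settings.
#' @param country,weight Column names.
#' @return Tibble with one row per dimension-measure pair.
#' @export
equity_table <- function(data, outcome, dimensions, B = 1000L, level = 0.95,
                         seed = 1L, country = "country_id", weight = "weight") {
  seeds <- split_seed(seed, length(dimensions))
  purrr::imap_dfr(dimensions, function(dim, nm) {
    s <- stratified_outcome(data, outcome, dim$subgroup, order = dim$order,
                            country = country, weight = weight)
    labs <- s$groups$subgroup
    adv <- dim$advantaged %||% as.character(labs[length(labs)])
    dis <- dim$disadvantaged %||% as.character(labs[1L])
    measures <- c("difference", "ratio",
                  if (s$ordered) c("ACI", "RCI", "SII", "RII"),
                  "PAR", "PAF")
    sub_seeds <- split_seed(seeds[which(names(dimensions) == nm)], length(measures))
    purrr::map2_dfr(measures, sub_seeds, function(msr, sd) {
      dplyr::mutate(
        cluster_bootstrap_ci(s, msr, B = B, level = level, seed = sd,
                             advantaged = adv, disadvantaged = dis,
                             link = dim$link %||% "logit",
                             reference = dim$reference %||% "best"),
        dimension = nm, .before = 1L)
    })
  })
}
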