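#' Normalized entropy of the posterior classifications
#'
#' Classification certainty at each level on the 0–1 scale:
#' \deqn{E_{low} = 1 - \frac{-\sum_i \sum_k P_{ik} \ln P_{ik}}{n \ln K},}
#' and analogously for the country level. By default the country-level score
#' sums over the J groups with denominator \eqn{J \ln M} (the scale on which a
#' perfectly classified country level reads 1.00);
#' `per_individual_higher = TRUE` instead sums each record's group posterior
#' with denominator \eqn{n \ln M}. One-class levels return 1 by convention and
#' \eqn{0 \ln 0 := 0}.
#'
#' @param posteriors An `mlca_posteriors` object.
#' @param per_individual_higher Use the per-record variant of the higher-level
#'   score.
#' @return Named numeric vector `c(E_low =, E_high =)`.
#' @export
entropy_scores <- function(posteriors, per_individual_higher = FALSE) {
  stopifnot(inherits(posteriors, "mlca_posteriors"))
  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)
  norm_entropy <- function(P, ncls) {
    if (ncls <= 1L) return(1)
    1 - (-sum(xlogx(P))) / (nrow(P) * log(ncls))
  }
  E_low <- norm_entropy(posteriors$indiv_post, posteriors$K)
  Pg <- if (per_individual_higher) {
    posteriors$group_post[posteriors$group_index, , drop = FALSE]
  } else posteriors$group_post
  E_high <- norm_entropy(Pg, posteriors$M)
  c(E_low = E_low, E_high = E_high)
}

#' Information criteria and entropy for one fitted model
#'
#' Computes, for a fitted measurement model with
#' \eqn{p = (M-1) + M(K-1) + KH} free parameters:
#' `AIC` \eqn{= -2\ell + 2p}, `BIC_low` \eqn{= -2\ell + p\ln n} (individuals),
#' `BIC_high` \eqn{= -2\ell + p\ln J} (countries), and
#' `ICL_BIC_high` \eqn{= BIC_{high} + 2\,EN_{high}} where
#' \eqn{EN_{high} = -\sum_j\sum_m P_{jm}\ln P_{jm}} is the country
#' classification entropy — so the two coincide exactly when countries are
#' classified with certainty.
#'
#' @param fit An `mlca_fit`.
#' @param n_low,n_high Sample sizes for the two BIC variants; default to the
#'   record and group counts of the fitted data.
#' @return A one-row tibble: `K, M, loglik, n_params, AIC, BIC_low, BIC_high,
#'   ICL_BIC_high, E_low, E_high`.
#' @export
information_criteria <- function(fit, n_low = fit$N, n_high = fit$J) {
  stopifnot(inherits(fit, "mlca_fit"))
  p <- mlca_n_params(fit$K, fit$M, fit$H)
  ll <- fit$loglik
  xlogx <- function(q) ifelse(q > 0, q * log(q), 0)
  EN_high <- -sum(xlogx(fit$posteriors$group_post))
  E <- entropy_scores(fit$posteriors)
  tibble(
    K = fit$K, M = fit$M, loglik = ll, n_params = p,
    AIC = -2 * ll + 2 * p,
    BIC_low = -2 * ll + p * log(n_low),
    BIC_high = -2 * ll + p * log(n_high),
    ICL_BIC_high = -2 * ll + p * log(n_high) + 2 * EN_high,
    E_low = unname(E["E_low"]), E_high = unname(E["E_high"]))
}

mlca_n_params <- function(K, M, H) (M - 1) + M * (K - 1) + K * H

#' Sequential selection of the class counts (K, M)
#'
#' Mirrors the study's sequential enumeration: sweep the individual-level
#' class count `K` with a single country class, fix the winner `K*`, sweep the
#' country-level count `M` at `K*`, then re-check `K` at the chosen `M*`
#' (reselection). The individual-level criterion defaults to `BIC_low` and the
#' country-level criterion to `BIC_high`; `"AIC"` uses AIC at both levels and
#' `"ICL"` uses `ICL_BIC_high` for the country level.
#'
#' @inheritParams fit_mlca
#' @param K_range,M_range Integer vectors of candidate class counts.
#' @param criterion `"BIC"`, `"AIC"` or `"ICL"`.
#' @param ... Passed to [fit_mlca()] (e.g. `n_starts`, `tol`, `seed`).
#' @return An `mlca_selection` list: `table` (one row per fitted model with a
#'   `stage` column), `chosen` (`c(K =, M =)`), `criterion`, and `fits` (the
#'   fitted models, named `"K2_M1"` etc.).
#' @export
select_structure <- function(data, K_range = 1:3, M_range = 1:3,
                             criterion = c("BIC", "AIC", "ICL"), ...) {
  criterion <- match.arg(criterion)
  if (!length(K_range) || !length(M_range)) abort("Class-count ranges must be non-empty.")
  crit_low <- if (criterion == "AIC") "AIC" else "BIC_low"
  crit_high <- switch(criterion, AIC = "AIC", BIC = "BIC_high", ICL = "ICL_BIC_high")
  fits <- list()
  rows <- list()
  fit_one <- function(K, M, stage) {
    key <- sprintf("K%d_M%d", K, M)
    if (is.null(fits[[key]])) fits[[key]] <<- fit_mlca(data, K = K, M = M, ...)
    rows[[length(rows) + 1L]] <<- dplyr::mutate(
      information_criteria(fits[[key]]), stage = stage)
    fits[[key]]
  }
  for (K in K_range) fit_one(K, min(M_range), "sweep_K")
  tab1 <- dplyr::bind_rows(rows)
  sweep1 <- dplyr::filter(tab1, .data$stage == "sweep_K")
  K_star <- sweep1$K[which.min(sweep1[[crit_low]])]
  for (M in setdiff(M_range, min(M_range))) fit_one(K_star, M, "sweep_M")
  tab2 <- dplyr::bind_rows(rows)
  sweepM <- dplyr::filter(tab2, .data$K == K_star)
  M_star <- sweepM$M[which.min(sweepM[[crit_high]])]
  for (K in setdiff(K_range, K_star)) fit_one(K, M_star, "recheck_K")
  table <- dplyr::bind_rows(rows)
  recheck <- dplyr::filter(table, .data$M == M_star)
  K_final <- recheck$K[which.min(recheck[[crit_low]])]
  structure(list(table = dplyr::distinct(table, .data$K, .data$M, .keep_all = TRUE),
                 chosen = c(K = K_final, M = M_star),
                 criterion = criterion, fits = fits),
            class = "mlca_selection")
}

#' @exportS3Method base::print
print.mlca_selection <- function(x, ...) {
  cat(sprintf("Sequential class enumeration (%s): chosen K = %d, M = %d\n",
              x$criterion, x$chosen["K"], x$chosen["M"]))
  print(dplyr::select(x$table, -dplyr::any_of("stage")))
  invisible(x)
}

# Adjusted Rand index between two hard classifications; uses mclust when
# installed, otherwise the standard pair-counting formula.
adjusted_rand <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

#' Sensitivity refits on conceptually separate indicator subsets
#'
#' Refits the `(K, M)` model on disjoint indicator subsets — by default
#' maternal care (antenatal through postnatal plus family planning) versus
#' child care (immunizations and breastfeeding) — and compares fit indices and
#' individual-level MAP agreement (adjusted Rand index) against the
#' full-indicator model.
#'
#' @inheritParams fit_mlca
#' @param partitions Named list of disjoint indicator-name vectors.
#' @param K,M Class counts to refit at.
#' @param ... Passed to [fit_mlca()].
#' @return A list: `models` (fit-index tibble, full model first), `agreement`
#'   (ARI of each subset's individual MAP against the full model's), `fits`.
#' @export
sensitivity_subsets <- function(data, partitions = default_partitions(),
                                K = 2L, M = 2L, ...) {
  all_ind <- unlist(partitions)
  if (anyDuplicated(all_ind)) abort("Indicator partitions must be disjoint.")
  missing_cols <- setdiff(all_ind, names(data))
  if (length(missing_cols))
    abort(paste0("Indicators not in data: ", paste(missing_cols, collapse = ", ")))
  for (nm in names(partitions)) {
    if (length(partitions[[nm]]) < 2)
      warn(sprintf("Subset '%s' has fewer than 2 indicators.", nm))
  }
  fits <- list(full = fit_mlca(data, K = K, M = M, indicators = all_ind, ...))
  for (nm in names(partitions)) {
    fits[[nm]] <- fit_mlca(data, K = K, M = M, indicators = partitions[[nm]], ...)
  }
  models <- purrr::imap_dfr(fits, function(f, nm)
    dplyr::mutate(information_criteria(f), model = nm, n_indicators = f$H,
                  .before = 1L))
  agreement <- purrr::imap_dfr(fits[-1L], function(f, nm)
    tibble(model = nm,
           ari_indiv = adjusted_rand(fits$full$posteriors$map_indiv,
                                     f$posteriors$map_indiv),
           ari_group = adjusted_rand(fits$full$posteriors$map_group,
                                     f$posteriors$map_group)))
  list(models = models, agreement = agreement, fits = fits)
}

default_partitions <- function() {
  list(maternal = c("anc", "tetanus", "facility_delivery", "skilled_attendant",
                    "pnc_mother", "pnc_newborn", "family_planning"),
       child = c("bcg", "dpt", "polio", "measles", "breastfeeding"))
}
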