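#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the item-response probabilities of a measurement fit
#'
#' @param x An `mlca_fit`.
#' @param ... Unused.
#' @return Long tibble `class, indicator, probability`.
#' @export
tidy.mlca_fit <- function(x, ...) {
  rho <- x$params$rho
  tibble(class = rep(class_labels(x$K, "lower"), times = ncol(rho)),
         indicator = rep(colnames(rho), each = nrow(rho)),
         probability = as.vector(rho))
}

#' One-row model summary of a measurement fit
#'
#' @param x An `mlca_fit`.
#' @param ... Unused.
#' @return One-row tibble of fit statistics and information criteria.
#' @export
glance.mlca_fit <- function(x, ...) {
  dplyr::mutate(information_criteria(x),
                N = x$N, J = x$J, converged = x$converged,
                n_iter = x$n_iter, best_of = x$best_of)
}

#' Tidy a structural fit into its odds-ratio table
#'
#' @param x An `mlca_structural`.
#' @param ... Passed to [odds_ratio_table()].
#' @return Tibble of adjusted odds ratios.
#' @export
tidy.mlca_structural <- function(x, ...) odds_ratio_table(x, ...)

#' @export
glance.mlca_structural <- function(x, ...) {
  tibble(loglik = x$loglik, n_iter = x$n_iter, converged = x$converged,
         separation_higher = unname(x$separation["higher"]),
         separation_lower = unname(x$separation["lower"]))
}

#' Tidy the fixed effects of a random-intercept logistic fit
#'
#' @param x An `ri_logit`.
#' @param ... Unused.
#' @return Tibble of fixed-effect odds ratios.
#' @export
tidy.ri_logit <- function(x, ...) x$fixed

#' @export
glance.ri_logit <- function(x, ...) {
  tibble(sigma2 = x$sigma2, sigma2_low = x$sigma2_ci[1L],
         sigma2_high = x$sigma2_ci[2L], ICC = x$ICC, MOR = x$MOR,
         loglik = x$loglik, boundary = x$boundary)
}

#' @export
tidy.mlca_selection <- function(x, ...) x$table

#' @export
tidy.strat_outcome <- function(x, ...) x$groups
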