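#' Measurement parameters of the two-level latent class model
#'
#' Bundles the three probability blocks of the model: country-class shares
#' `pi` (\eqn{\pi_m}), individual-class shares given the country class `tau`
#' (\eqn{\tau_{k|m}}, `M x K`, row-stochastic), and item-response
#' probabilities `rho` (\eqn{\rho_{hk}}, `K x H`). Item probabilities are
#' clamped to `[1e-6, 1 - 1e-6]` to keep log-likelihoods finite.
#'
#' @param pi,tau,rho Probability blocks as described above.
#' @return An object of class `mlca_params`.
#' @export
mlca_params <- function(pi, tau, rho) {
  pi <- as.numeric(pi); tau <- as.matrix(tau); rho <- as.matrix(rho)
  assert_prob_vector(pi, "pi", tol = 1e-10)
  if (nrow(tau) != length(pi)) abort("`tau` needs one row per country class.")
  for (m in seq_along(pi)) assert_prob_vector(tau[m, ], sprintf("tau[%d,]", m), tol = 1e-10)
  if (nrow(rho) != ncol(tau)) abort("`rho` needs one row per individual class.")
  if (any(rho < 0 | rho > 1)) abort("`rho` entries must lie in [0,1].")
  rho[] <- clamp_prob(rho)
  if (is.null(colnames(rho))) colnames(rho) <- paste0("y", seq_len(ncol(rho)))
  structure(list(pi = pi, tau = tau, rho = rho,
                 M = length(pi), K = ncol(tau), H = ncol(rho)),
            class = "mlca_params")
}

# Internal matrix view of a unit-record tibble: y (N x H with NA), contiguous
# group index, weights. Groups are re-indexed 1..J in order of appearance of
# the sorted unique ids.
as_lca_matrix <- function(data, indicators = NULL, group = "country_id",
                          weight = "weight") {
  if (!group %in% names(data)) abort(sprintf("Column `%s` not found.", group))
  indicators <- indicators %||% intersect(rmnch_indicators(), names(data))
  if (!length(indicators)) abort("No indicator columns found.")
  y <- as.matrix(data[indicators])
  if (!all(y %in% c(0, 1, NA))) abort("Indicator values must be 0, 1 or NA.")
  ids <- sort(unique(data[[group]]))
  g <- match(data[[group]], ids)
  w <- if (weight %in% names(data)) as.numeric(data[[weight]]) else rep(1, nrow(data))
  if (any(w <= 0)) abort("Weights must be positive.")
  list(y = y, g = g, w = w, J = length(ids), N = nrow(y), H = ncol(y),
       group_ids = ids, indicators = indicators)
}

# Per-record log density under each individual class: N x K.
record_logdens <- function(y, rho) {
  obs <- !is.na(y)
  y1 <- y; y1[!obs] <- 0
  y0 <- (1 - y); y0[!obs] <- 0
  y1 %*% t(log(rho)) + y0 %*% t(log(1 - rho))
}

# E-step quantities shared by loglik, posteriors and the EM.
# Returns per-record class-given-country mixtures and group posteriors.
estep_core <- function(mat, params) {
  lf <- record_logdens(mat$y, params$rho)            # N x K
  M <- params$M; K <- params$K
  A <- matrix(0, mat$N, M)                           # log sum_k tau e^lf
  for (m in seq_len(M)) {
    A[, m] <- row_logsumexp(sweep(lf, 2L, log(pmax(params$tau[m, ], 1e-300)), "+"))
  }
  Lg <- rowsum(mat$w * A, mat$g)                     # J x M weighted group terms
  rownames(Lg) <- NULL
  lj <- sweep(Lg, 2L, log(pmax(params$pi, 1e-300)), "+")
  lse <- row_logsumexp(lj)
  list(lf = lf, A = A, group_log = lj, loglik = sum(lse),
       group_post = exp(lj - lse))
}

#' Weighted log-likelihood of the two-level latent class model
#'
#' Computes \eqn{\sum_j \log \sum_m \pi_m \prod_{i \in j} \left[\sum_k
#' \tau_{k|m} \prod_h \rho_{hk}^{y_{ih}} (1-\rho_{hk})^{1-y_{ih}}\right]^{w_i}}
#' entirely in log space (log-sum-exp over classes at both levels). Missing
#' indicator cells contribute no factor, the model's missing-at-random
#' treatment.
#'
#' @param data Unit-record tibble with a country id column, optional `weight`
#'   column, and 0/1/NA indicator columns.
#' @param params An [mlca_params()] object.
#' @param indicators,group,weight Column selections; indicators default to the
#'   canonical 12 present in `data`.
#' @return Scalar log-likelihood.
#' @export
lca_loglik <- function(data, params, indicators = NULL,
                       group = "country_id", weight = "weight") {
  mat <- as_lca_matrix(data, indicators, group, weight)
  if (mat$H != params$H) abort("Indicator count does not match `params`.")
  estep_core(mat, params)$loglik
}

# Canonical labels: individual classes ordered by descending mean item
# probability ("optimal utilizers" first, tie-break on the first indicator);
# country classes by descending share of the optimal class ("high coverage"
# first).
canonicalize_params <- function(params) {
  ord_k <- order(-rowMeans(params$rho), -params$rho[, 1])
  rho <- params$rho[ord_k, , drop = FALSE]
  tau <- params$tau[, ord_k, drop = FALSE]
  ord_m <- order(-tau[, 1], -params$pi)
  lab_k <- class_labels(params$K, "lower")
  lab_m <- class_labels(params$M, "higher")
  rownames(rho) <- lab_k
  out <- mlca_params(setNames(params$pi[ord_m], lab_m),
                     tau[ord_m, , drop = FALSE], rho)
  dimnames(out$tau) <- list(lab_m, lab_k)
  out
}

init_params <- function(mat, K, M) {
  means <- clamp_prob(colMeans(mat$y, na.rm = TRUE))
  means[is.na(means)] <- 0.5
  rho <- matrix(clamp_prob(rep(means, each = K) +
                             runif(K * mat$H, -0.25, 0.25)), K, mat$H)
  colnames(rho) <- colnames(mat$y)
  dirich <- function(n) { x <- rgamma(n, 1); x / sum(x) }
  tau <- matrix(rgamma(M * K, 1), M, K)
  tau <- tau / rowSums(tau)
  mlca_params(dirich(M), tau, rho)
}

em_once <- function(mat, K, M, tol, max_iter) {
  params <- init_params(mat, K, M)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    e <- estep_core(mat, params)
    ll <- e$loglik
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
    # M-step from the joint posteriors q_imk = P_{j(i),m} * P(C_i = k | m, y_i)
    Pg_i <- e$group_post[mat$g, , drop = FALSE]        # N x M
    pi_new <- colMeans(e$group_post)
    tau_new <- matrix(0, M, K)
    num_rho <- matrix(0, K, mat$H)
    den_rho <- matrix(0, K, mat$H)
    obs <- !is.na(mat$y)
    y1 <- mat$y; y1[!obs] <- 0
    Pik <- matrix(0, mat$N, K)
    for (m in seq_len(M)) {
      B <- exp(sweep(sweep(e$lf, 2L, log(pmax(params$tau[m, ], 1e-300)), "+"),
                     1L, e$A[, m], "-"))               # N x K, rows sum to 1
      q_m <- B * Pg_i[, m]
      Pik <- Pik + q_m
      tau_new[m, ] <- colSums(mat$w * q_m)
    }
    tau_new <- tau_new / pmax(rowSums(tau_new), 1e-300)
    wP <- mat$w * Pik
    num_rho <- t(wP) %*% y1
    den_rho <- t(wP) %*% obs
    rho_new <- clamp_prob(num_rho / pmax(den_rho, 1e-300))
    colnames(rho_new) <- colnames(mat$y)
    params <- mlca_params(pmax(pi_new, 1e-12) / sum(pmax(pi_new, 1e-12)),
                          tau_new, rho_new)
  }
  list(params = params, loglik = ll, n_iter = iter, converged = converged,
       ll_trace = ll_trace)
}

#' Fit the two-level latent class measurement model by EM
#'
#' Estimates \eqn{(\pi, \tau, \rho)} without covariates by
#' expectation-maximization from `n_starts` random initializations (item
#' probabilities from perturbed overall means, class shares from symmetric
#' Dirichlet draws), keeping the restart with the highest weighted
#' log-likelihood. Record weights act as frequency weights. Classes are
#' canonicalized so the first individual class is the high-utilization
#' ("optimal") profile and the first country class has the largest optimal
#' share.
#'
#' @inheritParams lca_loglik
#' @param K,M Number of individual-level and country-level classes.
#' @param n_starts Random restarts (default 20).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @param seed Integer seed governing all restarts.
#' @param verbose Print one line per restart with its final log-likelihood.
#' @return An object of class `mlca_fit`: `params`, `posteriors` (see
#'   [compute_posteriors()]), `loglik`, `n_iter`, `converged`, `best_of`,
#'   `restart_logliks`, `seed`, plus the problem sizes `N`, `J`, `H`, `K`, `M`.
#' @export
fit_mlca <- function(data, K, M = 1L, n_starts = 20L, tol = 1e-8,
                     max_iter = 1000L, seed = 1L, indicators = NULL,
                     group = "country_id", weight = "weight", verbose = FALSE) {
  if (K < 1 || M < 1) abort("`K` and `M` must be >= 1.")
  mat <- as_lca_matrix(data, indicators, group, weight)
  if (mat$N < K) abort("Need at least K records.")
  n_patterns <- nrow(unique(mat$y))
  boundary <- FALSE
  if (K > n_patterns || M > mat$J) {
    warn("Requested more classes than distinguishable patterns; fit flagged as boundary.")
    boundary <- TRUE
  }
  seeds <- split_seed(seed, n_starts)
  best <- NULL
  restart_ll <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    set.seed(seeds[s])
    res <- em_once(mat, K, M, tol, max_iter)
    restart_ll[s] <- res$loglik
    if (verbose) message(sprintf("restart %d/%d: loglik %.6f", s, n_starts, res$loglik))
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  params <- canonicalize_params(best$params)
  post <- posteriors_from_mat(mat, params)
  structure(
    list(params = params, posteriors = post, loglik = best$loglik,
         n_iter = best$n_iter, converged = best$converged && !boundary,
         boundary = boundary, best_of = n_starts, restart_logliks = restart_ll,
         ll_trace = best$ll_trace, seed = seed,
         N = mat$N, J = mat$J, H = mat$H, K = K, M = M,
         sum_weights = sum(mat$w), indicators = mat$indicators,
         group_ids = mat$group_ids, weights = mat$w, group_index = mat$g),
    class = "mlca_fit")
}

posteriors_from_mat <- function(mat, params) {
  e <- estep_core(mat, params)
  M <- params$M; K <- params$K
  joint <- array(0, c(mat$N, M, K))
  Pg_i <- e$group_post[mat$g, , drop = FALSE]
  for (m in seq_len(M)) {
    B <- exp(sweep(sweep(e$lf, 2L, log(pmax(params$tau[m, ], 1e-300)), "+"),
                   1L, e$A[, m], "-"))
    joint[, m, ] <- B * Pg_i[, m]
  }
  indiv <- apply(joint, c(1L, 3L), sum)
  structure(
    list(group_post = e$group_post, joint_post = joint, indiv_post = indiv,
         map_group = max.col(e$group_post, ties.method = "first"),
         map_indiv = max.col(indiv, ties.method = "first"),
         group_ids = mat$group_ids, group_index = mat$g, weights = mat$w,
         loglik = e$loglik, K = K, M = M),
    class = "mlca_posteriors")
}

#' Posterior class probabilities and MAP assignments at both levels
#'
#' Applies Bayes' rule at fixed parameters: country posteriors
#' \eqn{P_{jm} \propto \pi_m f(\mathbf{y}_j \mid m)}, joint record posteriors
#' \eqn{q_{imk} = P_{j(i)m} \, P(C_i = k \mid m, y_i)}, and marginal
#' individual posteriors \eqn{P_{ik} = \sum_m q_{imk}}. MAP ties break toward
#' the lower class index.
#'
#' @inheritParams lca_loglik
#' @return An `mlca_posteriors` object: `group_post` (`J x M`), `joint_post`
#'   (`N x M x K`), `indiv_post` (`N x K`), `map_group`, `map_indiv`.
#' @export
compute_posteriors <- function(data, params, indicators = NULL,
                               group = "country_id", weight = "weight") {
  mat <- as_lca_matrix(data, indicators, group, weight)
  if (mat$H != params$H) abort("Indicator count does not match `params`.")
  posteriors_from_mat(mat, params)
}

class_labels <- function(n, level) {
  if (level == "lower" && n == 2) return(c("optimal", "suboptimal"))
  if (level == "higher" && n == 2) return(c("high_coverage", "low_coverage"))
  paste0(if (level == "lower") "L" else "H", seq_len(n))
}

#' Class-proportion tables from posterior probabilities
#'
#' Produces the reporting tables of the analysis: (a) country-class shares
#' (mean group posterior), (b) individual-class shares conditional on the
#' country class (posterior- and record-weight-weighted), (c) overall
#' individual-class shares, and (d) the per-country MAP assignment listing.
#'
#' @param posteriors An `mlca_posteriors` object.
#' @param weights Optional record weights overriding those captured at fit
#'   time.
#' @return A list of tibbles `higher`, `lower_given_higher`, `lower`,
#'   `assignments`.
#' @export
summarize_classes <- function(posteriors, weights = NULL) {
  stopifnot(inherits(posteriors, "mlca_posteriors"))
  K <- posteriors$K; M <- posteriors$M
  w <- weights %||% posteriors$weights
  lab_k <- class_labels(K, "lower"); lab_m <- class_labels(M, "higher")
  higher <- tibble(class = lab_m, share = colMeans(posteriors$group_post))
  cond <- matrix(0, M, K)
  for (m in seq_len(M)) {
    qm <- posteriors$joint_post[, m, , drop = FALSE]
    dim(qm) <- c(dim(posteriors$joint_post)[1L], K)
    cond[m, ] <- colSums(w * qm)
  }
  cond <- cond / pmax(rowSums(cond), 1e-300)
  lower_given_higher <- tibble(
    higher_class = rep(lab_m, each = K),
    lower_class = rep(lab_k, M),
    share = as.vector(t(cond)))
  lower <- tibble(class = lab_k,
                  share = colSums(w * posteriors$indiv_post) / sum(w))
  assignments <- dplyr::bind_cols(
    tibble(country_id = posteriors$group_ids,
           map_class = lab_m[posteriors$map_group]),
    as_tibble(setNames(as.data.frame(posteriors$group_post), paste0("P_", lab_m))))
  list(higher = higher, lower_given_higher = lower_given_higher,
       lower = lower, assignments = assignments)
}

#' @exportS3Method base::print
print.mlca_fit <- function(x, ...) {
  cat(sprintf("Two-level latent class model: K = %d, M = %d\n", x$K, x$M))
  cat(sprintf("N = %d records in J = %d groups, %d indicators\n", x$N, x$J, x$H))
  cat(sprintf("loglik = %.4f after %d EM iterations (best of %d starts)%s\n",
              x$loglik, x$n_iter, x$best_of,
              if (x$converged) "" else " [not converged]"))
  cat("\nCountry-class shares (pi):\n")
  print(round(setNames(x$params$pi, class_labels(x$M, "higher")), 3))
  cat("\nIndividual-class shares given country class (tau):\n")
  tau <- x$params$tau
  dimnames(tau) <- list(class_labels(x$M, "higher"), class_labels(x$K, "lower"))
  print(round(tau, 3))
  invisible(x)
}

#' @exportS3Method base::print
print.mlca_params <- function(x, ...) {
  cat(sprintf("mlca_params: M = %d, K = %d, H = %d\n", x$M, x$K, x$H))
  cat("pi:", paste(round(x$pi, 3), collapse = ", "), "\n")
  invisible(x)
}
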