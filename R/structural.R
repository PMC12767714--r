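# Weighted multinomial logistic regression by ridge-stabilized Newton-Raphson.
# Wt is an n x C matrix of nonnegative fractional class weights; the last
# class is the reference. Returns (C-1) x p coefficients, the inverse
# information as vcov, and a separation flag (any |coef| > 15 on the logit
# scale).
multinom_ridge <- function(X, Wt, ridge = 1e-6, max_iter = 100L, tol = 1e-10,
                           start = NULL) {
  n <- nrow(X); p <- ncol(X); C <- ncol(Wt)
  r <- rowSums(Wt)
  B <- start %||% matrix(0, C - 1L, p)
  npar <- (C - 1L) * p
  loglik <- function(B) {
    eta <- cbind(X %*% t(B), 0)
    sum(Wt * (eta - row_logsumexp(eta)))
  }
  ll_old <- loglik(B)
  for (it in seq_len(max_iter)) {
    eta <- cbind(X %*% t(B), 0)
    P <- exp(eta - row_logsumexp(eta))
    grad <- numeric(npar)
    H <- matrix(0, npar, npar)
    for (cc in seq_len(C - 1L)) {
      idx <- ((cc - 1L) * p + 1L):(cc * p)
      grad[idx] <- colSums(X * (Wt[, cc] - r * P[, cc]))
      for (dd in seq_len(C - 1L)) {
        jdx <- ((dd - 1L) * p + 1L):(dd * p)
        wcd <- r * (P[, cc] * ((cc == dd) - P[, dd]))
        H[idx, jdx] <- crossprod(X, X * wcd)
      }
    }
    H <- H + diag(ridge, npar)
    step <- solve(H, grad)
    B_new <- B + matrix(step, C - 1L, p, byrow = TRUE)
    ll_new <- loglik(B_new)
    # halve the step if the penalized objective worsens
    h <- 0
    while (ll_new < ll_old - 1e-12 && h < 30) {
      step <- step / 2; h <- h + 1
      B_new <- B + matrix(step, C - 1L, p, byrow = TRUE)
      ll_new <- loglik(B_new)
    }
    conv <- abs(ll_new - ll_old) <= tol * (abs(ll_old) + 1e-3)
    B <- B_new; ll_old <- ll_new
    if (conv) break
  }
  dimnames(B) <- list(NULL, colnames(X))
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, npar, npar))
  list(coef = B, vcov = vc, loglik = ll_old, converged = conv,
       separation = any(abs(B) > 15))
}

design_matrix <- function(data, covariates) {
  if (!length(covariates)) return(stats::model.matrix(~ 1, data))
  stats::model.matrix(stats::reformulate(covariates), data)
}

#' Two-step structural estimation: covariates on class membership
#'
#' With the measurement parameters (item probabilities `rho`) held fixed at a
#' previously fitted measurement model, maximizes the model likelihood over
#' the membership regressions only: a multinomial logit of the country class
#' on country-level covariates, and, within each country class `m`, a
#' multinomial logit of the individual class on individual-level covariates.
#' Estimation is by EM whose M-step solves posterior-weighted multinomial
#' logistic problems (Newton-Raphson with a 1e-6 ridge). The reference
#' category at each level is the canonical last ("low coverage" /
#' "suboptimal") class, so positive coefficients mean higher odds of the
#' optimal/high-coverage class. Wald covariances come from the information of
#' the converged weighted logistic problems; step-1 (measurement) uncertainty
#' is ignored, the usual two-step trade-off.
#'
#' @param data Unit-record tibble (indicators + individual covariates).
#' @param measurement An [mlca_params()] object (or the `params` of an
#'   `mlca_fit`) from the measurement step.
#' @param indiv_covariates Character vector of individual-level covariate
#'   columns in `data` (may be empty for intercept-only).
#' @param group_covariates Character vector of country-level covariate columns
#'   in `country_data`.
#' @param country_data Tibble `country_id` + country covariates; required when
#'   `group_covariates` is non-empty.
#' @param indicators,group,weight Column selections as in [fit_mlca()].
#' @param tol,max_iter EM convergence controls.
#' @return An object of class `mlca_structural`: `alpha` (higher-level
#'   coefficients, one row per non-reference country class), `gamma` (list
#'   over country classes of individual-level coefficient matrices),
#'   `vcov_alpha`, `vcov_gamma`, `loglik`, `converged`, `separation` flags,
#'   and the fitted membership probabilities.
#' @export
fit_two_step <- function(data, measurement, indiv_covariates = character(),
                         group_covariates = character(), country_data = NULL,
                         indicators = NULL, group = "country_id",
                         weight = "weight", tol = 1e-8, max_iter = 200L) {
  params <- if (inherits(measurement, "mlca_fit")) measurement$params else measurement
  stopifnot(inherits(params, "mlca_params"))
  mat <- as_lca_matrix(data, indicators, group, weight)
  if (mat$H != params$H) abort("Indicator count does not match the measurement model.")
  M <- params$M; K <- params$K
  X2 <- design_matrix(data, indiv_covariates)
  if (length(group_covariates)) {
    if (is.null(country_data)) abort("`country_data` is required for group covariates.")
    cd <- country_data[match(mat$group_ids, country_data$country_id), , drop = FALSE]
    X1 <- design_matrix(cd, group_covariates)
  } else X1 <- matrix(1, mat$J, 1L, dimnames = list(NULL, "(Intercept)"))

  lf <- record_logdens(mat$y, params$rho)              # fixed step-1 densities
  # initialize from the measurement-model shares
  alpha <- matrix(0, max(M - 1L, 0L), ncol(X1), dimnames = list(NULL, colnames(X1)))
  if (M > 1L) alpha[, 1L] <- log(params$pi[-M] / params$pi[M])
  gamma <- lapply(seq_len(M), function(m) {
    g <- matrix(0, max(K - 1L, 0L), ncol(X2), dimnames = list(NULL, colnames(X2)))
    if (K > 1L) g[, 1L] <- log(params$tau[m, -K] / params$tau[m, K])
    g
  })
  logprob <- function(X, B) {                          # n x C log class probs
    eta <- cbind(X %*% t(B), 0)
    eta - row_logsumexp(eta)
  }
  ll_old <- -Inf; converged <- FALSE
  fit_high <- NULL; fit_low <- vector("list", M)
  for (it in seq_len(max_iter)) {
    lp1 <- if (M > 1L) logprob(X1, alpha) else matrix(0, mat$J, 1L)
    A <- matrix(0, mat$N, M)
    cond <- vector("list", M)                          # P(C=k | m, y_i, Z2_i)
    for (m in seq_len(M)) {
      lp2 <- if (K > 1L) logprob(X2, gamma[[m]]) else matrix(0, mat$N, 1L)
      s <- lp2 + lf
      A[, m] <- row_logsumexp(s)
      cond[[m]] <- exp(s - A[, m])
    }
    lj <- lp1 + rowsum(mat$w * A, mat$g)
    lse <- row_logsumexp(lj)
    ll <- sum(lse)
    Pg <- exp(lj - lse)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    if (M > 1L) {
      fit_high <- multinom_ridge(X1, Pg, start = alpha)
      alpha <- fit_high$coef
    }
    Pg_i <- Pg[mat$g, , drop = FALSE]
    for (m in seq_len(M)) {
      if (K > 1L) {
        Wt <- mat$w * Pg_i[, m] * cond[[m]]
        fit_low[[m]] <- multinom_ridge(X2, Wt, start = gamma[[m]])
        gamma[[m]] <- fit_low[[m]]$coef
      }
    }
  }
  lab_m <- class_labels(M, "higher"); lab_k <- class_labels(K, "lower")
  if (M > 1L) rownames(alpha) <- lab_m[-M]
  for (m in seq_len(M)) if (K > 1L) rownames(gamma[[m]]) <- lab_k[-K]
  names(gamma) <- lab_m
  structure(
    list(alpha = alpha, gamma = gamma,
         vcov_alpha = if (!is.null(fit_high)) fit_high$vcov,
         vcov_gamma = lapply(fit_low, function(f) if (!is.null(f)) f$vcov),
         loglik = ll_old, n_iter = it, converged = converged,
         separation = c(higher = !is.null(fit_high) && fit_high$separation,
                        lower = any(vapply(fit_low,
                                           function(f) !is.null(f) && f$separation,
                                           logical(1)))),
         group_post = Pg, M = M, K = K,
         ref_higher = lab_m[M], ref_lower = lab_k[K],
         measurement = params),
    class = "mlca_structural")
}

# Fitted class-membership probabilities at covariate values (lower level
# within country class m).
predict_membership <- function(object, newdata = NULL, level = c("lower", "higher"),
                               m = 1L, covariates = NULL) {
  level <- match.arg(level)
  B <- if (level == "lower") object$gamma[[m]] else object$alpha
  X <- if (is.null(newdata)) matrix(1, 1L, 1L, dimnames = list(NULL, "(Intercept)"))
       else design_matrix(newdata, covariates %||% setdiff(colnames(B), "(Intercept)"))
  eta <- cbind(X[, colnames(B), drop = FALSE] %*% t(B), 0)
  exp(eta - row_logsumexp(eta))
}

#' Adjusted odds-ratio table from a structural fit
#'
#' Exponentiates the structural coefficients into adjusted odds ratios with
#' Wald confidence intervals and p-values, stratified by country class for the
#' individual-level model.
#'
#' @param params An `mlca_structural` fit.
#' @param level Confidence level (default 0.95).
#' @return Tibble with columns `level` ("country" or "individual"), `stratum`
#'   (country class for individual-level rows), `term`, `estimate` (log-odds),
#'   `AOR`, `CI_low`, `CI_high`, `p`.
#' @export
odds_ratio_table <- function(params, level = 0.95) {
  stopifnot(inherits(params, "mlca_structural"))
  z <- qnorm(1 - (1 - level) / 2)
  one_block <- function(B, V, lev, stratum) {
    if (is.null(B) || !nrow(B)) return(NULL)
    se <- if (is.null(V) || anyNA(V)) rep(NA_real_, length(B))
          else sqrt(pmax(diag(V), 0))
    est <- as.vector(t(B))   # row-major: class 1 terms, class 2 terms, ...
    tibble(level = lev, stratum = stratum,
           class = rep(rownames(B), each = ncol(B)),
           term = rep(colnames(B), nrow(B)),
           estimate = est, se = se,
           AOR = exp(est),
           CI_low = exp(est - z * se), CI_high = exp(est + z * se),
           p = 2 * pnorm(-abs(est / se)))
  }
  out <- list(one_block(params$alpha, params$vcov_alpha, "country", NA_character_))
  for (m in seq_along(params$gamma)) {
    out[[length(out) + 1L]] <- one_block(params$gamma[[m]], params$vcov_gamma[[m]],
                                         "individual", names(params$gamma)[m])
  }
  dplyr::bind_rows(out)
}

#' Random-intercept logistic regression with ICC and MOR summaries
#'
#' Fits a logistic mixed model with a country random intercept by adaptive
#' Gauss-Hermite quadrature (via `lme4::glmer`, default 15 nodes), and
#' summarizes between-country heterogeneity with the latent-scale intraclass
#' correlation and the median odds ratio (see [mor_icc()]). The variance CI is
#' a profile interval on the random-effect standard deviation, squared.
#'
#' @param data Tibble with the outcome, grouping and covariate columns.
#' @param outcome Name of the binary (0/1) outcome column.
#' @param group Name of the grouping column (>= 2 groups required).
#' @param covariates Character vector of fixed-effect covariate columns.
#' @param nAGQ Number of quadrature nodes.
#' @param ci `"profile"` for a profile CI on the variance, `"none"` to skip.
#' @param level Confidence level.
#' @return Object of class `ri_logit`: `sigma2`, `sigma2_ci`, `ICC`, `MOR`,
#'   `fixed` (odds-ratio tibble), `loglik`, `boundary` flag, and the
#'   underlying `glmerMod` as `$model`.
#' @export
fit_random_intercept_logistic <- function(data, outcome, group = "country_id",
                                          covariates = character(), nAGQ = 15L,
                                          ci = c("profile", "none"), level = 0.95) {
  ci <- match.arg(ci)
  if (length(unique(data[[group]])) < 2L) abort("Need at least 2 groups.")
  rhs <- paste(c(if (length(covariates)) covariates else "1",
                 sprintf("(1 | %s)", group)), collapse = " + ")
  form <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- lme4::glmer(form, data = data, family = binomial(), nAGQ = nAGQ)
  vc <- lme4::VarCorr(fit)
  sigma2 <- as.numeric(vc[[group]][1L, 1L])
  boundary <- sigma2 < 1e-8
  sigma2_ci <- c(NA_real_, NA_real_)
  if (ci == "profile") {
    sd_ci <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::confint.merMod(fit, parm = "theta_", method = "profile",
                             level = level, quiet = TRUE))),
      error = function(e) NULL)
    if (!is.null(sd_ci)) sigma2_ci <- as.numeric(sd_ci[1L, ])^2
  }
  im <- mor_icc(sigma2)
  z <- qnorm(1 - (1 - level) / 2)
  co <- summary(fit)$coefficients
  fixed <- tibble(term = rownames(co), estimate = co[, 1L], se = co[, 2L],
                  AOR = exp(co[, 1L]),
                  CI_low = exp(co[, 1L] - z * co[, 2L]),
                  CI_high = exp(co[, 1L] + z * co[, 2L]),
                  p = co[, 4L])
  structure(list(sigma2 = sigma2, sigma2_ci = sigma2_ci,
                 ICC = im$ICC, MOR = im$MOR, fixed = fixed,
                 loglik = as.numeric(logLik(fit)), boundary = boundary,
                 nAGQ = nAGQ, model = fit),
            class = "ri_logit")
}

#' @exportS3Method base::print
print.ri_logit <- function(x, ...) {
  cat(sprintf("Random-intercept logistic model (nAGQ = %d)\n", x$nAGQ))
  cat(sprintf("sigma^2 = %.4f (%.4f, %.4f)%s\n", x$sigma2,
              x$sigma2_ci[1], x$sigma2_ci[2],
              if (x$boundary) " [boundary]" else ""))
  cat(sprintf("ICC = %.2f%%, MOR = %.2f\n", 100 * x$ICC, x$MOR))
  invisible(x)
}

#' Intraclass correlation and median odds ratio from a logit-scale variance
#'
#' For a random-intercept variance \eqn{\sigma^2} on the logit scale:
#' \deqn{ICC = \frac{\sigma^2}{\sigma^2 + \pi^2/3}, \qquad
#'       MOR = \exp\!\left(\sqrt{2\sigma^2}\,\Phi^{-1}(0.75)\right).}
#' The ICC is the share of latent outcome variance attributable to the
#' grouping; the MOR is the median odds ratio between two identical
#' individuals from two randomly drawn groups.
#'
#' @param sigma2 Nonnegative variance on the logit scale.
#' @return One-row tibble `sigma2, ICC, MOR`.
#' @export
mor_icc <- function(sigma2) {
  if (!is.numeric(sigma2) || length(sigma2) != 1L || is.na(sigma2) || sigma2 < 0)
    abort("`sigma2` must be a single nonnegative number.")
  tibble(sigma2 = sigma2,
         ICC = sigma2 / (sigma2 + pi^2 / 3),
         MOR = exp(sqrt(2 * sigma2) * qnorm(0.75)))
}
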