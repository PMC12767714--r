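#' Build a simulation configuration for a two-level latent class population
#'
#' Describes a population of women nested in countries with a discrete latent
#' class at each level: country class \eqn{W_j \sim \pi}, individual class
#' \eqn{C_i \mid W_j = m \sim \tau_{\cdot|m}}, and binary service indicators
#' \eqn{y_{ih} \sim \mathrm{Bern}(\rho_{h,C_i})} independent given the class.
#' Covariates may shift membership at either level through multinomial-logit
#' models whose reference category is the last (canonically "low"/"suboptimal")
#' class; intercepts are derived from `pi` and `tau` so that zero covariate
#' effects reproduce the marginal class proportions exactly.
#'
#' @param J Number of country groups (>= 1).
#' @param group_sizes Scalar (every group the same size), an integer vector of
#'   length `J`, or `list(type = "lognormal", mean =, sdlog =)` for random
#'   unequal sizes scaled to the requested mean.
#' @param pi Length-`M` country-class probability vector.
#' @param tau `M x K` row-stochastic matrix of individual-class probabilities
#'   given the country class.
#' @param rho `K x H` matrix of item-response probabilities; column names name
#'   the indicators.
#' @param alpha Optional `(M-1) x P1` matrix of country-level covariate effects
#'   on the country-class logits (columns named after country covariates).
#' @param gamma Optional list of length `M`, each element a `(K-1) x P2` matrix
#'   of individual-level covariate effects within that country class.
#' @param covariates List with elements `individual` and `country`, each a
#'   named list of distribution specs: `list(type = "binary", p =)` or
#'   `list(type = "normal", mean =, sd =)`.
#' @param weights `NULL` for unit weights or `list(type = "gamma", shape =)`
#'   for mean-one gamma survey-style weights.
#' @param seed Master integer seed; one seed governs all draws through a fixed
#'   stream-splitting rule.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(J, group_sizes, pi, tau, rho,
                       alpha = NULL, gamma = NULL,
                       covariates = list(individual = list(), country = list()),
                       weights = NULL, seed = 1L) {
  if (!is.numeric(J) || length(J) != 1L || J < 1) abort("`J` must be a single integer >= 1.")
  J <- as.integer(J)
  pi <- as.numeric(pi)
  assert_prob_vector(pi, "pi")
  tau <- as.matrix(tau)
  M <- length(pi)
  K <- ncol(tau)
  if (nrow(tau) != M) abort("`tau` must have one row per country class.")
  for (m in seq_len(M)) assert_prob_vector(tau[m, ], sprintf("tau[%d,]", m))
  rho <- as.matrix(rho)
  if (nrow(rho) != K) abort("`rho` must have one row per individual class.")
  if (any(rho < 0 | rho > 1)) abort("`rho` entries must lie in [0, 1].")
  if (is.null(colnames(rho))) colnames(rho) <- paste0("y", seq_len(ncol(rho)))
  sizes <- validate_group_sizes(group_sizes, J)
  if (!is.null(alpha)) alpha <- as.matrix(alpha)
  if (!is.null(gamma)) {
    if (!is.list(gamma) || length(gamma) != M) abort("`gamma` must be a list of length M.")
    gamma <- lapply(gamma, as.matrix)
  }
  structure(
    list(J = J, group_sizes = sizes, M = M, K = K, H = ncol(rho),
         pi = pi, tau = tau, rho = rho, alpha = alpha, gamma = gamma,
         covariates = covariates, weights = weights, seed = as.integer(seed)),
    class = "sim_config")
}

validate_group_sizes <- function(group_sizes, J) {
  if (is.list(group_sizes)) {
    if (!identical(group_sizes$type, "lognormal"))
      abort("Random `group_sizes` must be list(type = \"lognormal\", mean =, sdlog =).")
    if (is.null(group_sizes$mean) || group_sizes$mean < 1)
      abort("lognormal group sizes need a mean >= 1.")
    group_sizes$sdlog <- group_sizes$sdlog %||% 0.5
    return(group_sizes)
  }
  group_sizes <- as.integer(group_sizes)
  if (any(group_sizes < 1)) abort("Group sizes must be >= 1.")
  if (!length(group_sizes) %in% c(1L, J))
    abort("`group_sizes` must be a scalar or length-J vector.")
  if (length(group_sizes) == 1L) rep(group_sizes, J) else group_sizes
}

#' Default configuration encoding the published two-class utilization profile
#'
#' Returns a [sim_config()] whose class structure matches the fitted two-level,
#' two-class model reported for 29 sub-Saharan African countries: country-class
#' shares 65.6% / 34.4%, optimal-utilizer shares of 82.7% (high-coverage
#' countries) and 46.5% (low-coverage countries), and the eleven published
#' class-conditional service probabilities (e.g. facility delivery 0.97 vs
#' 0.20, skilled attendance 0.98 vs 0.25). The tetanus-toxoid pair is never
#' published; the default (0.55, 0.30) is a free choice of this package, not a
#' reported value. Covariate effects default to zero.
#'
#' @param J Number of country groups (default 29, the study's country count).
#' @param n_per_group Records per group, a scalar, length-`J` vector, or
#'   lognormal spec as in [sim_config()].
#' @param seed Master seed.
#' @param weights Optional weight spec passed to [sim_config()].
#' @return A `sim_config`.
#' @export
rmnch_config <- function(J = 29L, n_per_group = 500L, seed = 1L, weights = NULL) {
  if (!is.numeric(J) || length(J) != 1L || J < 2) abort("`J` must be an integer >= 2.")
  if (!is.list(n_per_group) && any(n_per_group < 1)) abort("`n_per_group` must be >= 1.")
  rho <- rbind(
    optimal    = c(anc = 0.25, tetanus = 0.55, facility_delivery = 0.97,
                   skilled_attendant = 0.98, pnc_mother = 0.73, pnc_newborn = 0.76,
                   bcg = 0.97, dpt = 0.87, polio = 0.77, measles = 0.86,
                   breastfeeding = 0.66, family_planning = 0.41),
    suboptimal = c(anc = 0.12, tetanus = 0.30, facility_delivery = 0.20,
                   skilled_attendant = 0.25, pnc_mother = 0.10, pnc_newborn = 0.09,
                   bcg = 0.60, dpt = 0.39, polio = 0.38, measles = 0.44,
                   breastfeeding = 0.63, family_planning = 0.15))
  sim_config(
    J = J, group_sizes = n_per_group,
    pi = c(0.656, 0.344),
    tau = rbind(high = c(0.827, 0.173), low = c(0.465, 0.535)),
    rho = rho,
    covariates = list(
      individual = list(urban = list(type = "binary", p = 0.35)),
      country = list(gdp = list(type = "normal", mean = 0, sd = 1))),
    weights = weights, seed = seed)
}

draw_covariates <- function(spec, n) {
  if (length(spec) == 0) return(tibble(.rows = n))
  cols <- lapply(spec, function(s) {
    switch(s$type,
      binary = rbinom(n, 1L, s$p %||% 0.5),
      normal = rnorm(n, s$mean %||% 0, s$sd %||% 1),
      abort(sprintf("Unknown covariate type '%s'.", s$type)))
  })
  as_tibble(cols)
}

# Multinomial-logit class probabilities with reference category = last class.
# intercepts come from the marginal proportions so zero effects reproduce them.
membership_probs <- function(base, effects, X) {
  ncls <- length(base)
  n <- nrow(X)
  eta <- matrix(log(base[-ncls] / base[ncls]), n, ncls - 1L, byrow = TRUE)
  if (!is.null(effects) && ncol(X) > 0) {
    eta <- eta + as.matrix(X[, colnames(effects), drop = FALSE]) %*% t(effects)
  }
  eta <- cbind(eta, 0)
  p <- exp(eta - row_logsumexp(eta))
  p / rowSums(p)
}

#' Simulate a two-level latent class population
#'
#' Draws country classes, individual classes within countries, and binary
#' service indicators from a [sim_config()], returning the unit-record data
#' together with the latent ground truth for recovery testing. Identical
#' configurations (including seed) give bit-identical output.
#'
#' @param config A `sim_config`.
#' @return A list of class `rmnch_sim` with elements `data` (tibble: one row
#'   per record with `record_id`, `country_id`, `weight`, indicator columns and
#'   individual covariates), `country_data` (tibble of country covariates),
#'   `truth` (list with `groups` = tibble(country_id, W) and `records` =
#'   tibble(record_id, C)), and `config`.
#' @export
simulate_rmnch <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must come from sim_config().")
  seeds <- split_seed(config$seed, 6L)
  J <- config$J; M <- config$M; K <- config$K; H <- config$H

  set.seed(seeds[1])
  sizes <- if (is.list(config$group_sizes)) {
    pmax(1L, as.integer(round(rlnorm(J, meanlog = log(config$group_sizes$mean) -
                                       config$group_sizes$sdlog^2 / 2,
                                     sdlog = config$group_sizes$sdlog))))
  } else config$group_sizes
  N <- sum(sizes)

  set.seed(seeds[2])
  Z1 <- draw_covariates(config$covariates$country %||% list(), J)
  pW <- membership_probs(config$pi, config$alpha, Z1)
  W <- apply(pW, 1L, function(p) sample.int(M, 1L, prob = p))

  set.seed(seeds[3])
  country_id <- rep(seq_len(J), sizes)
  Z2 <- draw_covariates(config$covariates$individual %||% list(), N)
  C <- integer(N)
  for (m in seq_len(M)) {
    idx <- which(W[country_id] == m)
    if (!length(idx)) next
    pC <- membership_probs(config$tau[m, ], config$gamma[[m]], Z2[idx, , drop = FALSE])
    C[idx] <- apply(pC, 1L, function(p) sample.int(K, 1L, prob = p))
  }

  set.seed(seeds[4])
  y <- matrix(rbinom(N * H, 1L, t(config$rho)[, C]), nrow = N, ncol = H, byrow = TRUE)
  colnames(y) <- colnames(config$rho)

  set.seed(seeds[5])
  w <- if (is.null(config$weights)) rep(1, N) else {
    sh <- config$weights$shape %||% 4
    rgamma(N, shape = sh, rate = sh)
  }

  data <- dplyr::bind_cols(
    tibble(record_id = seq_len(N), country_id = country_id, weight = w),
    as_tibble(y), Z2)
  structure(
    list(data = data,
         country_data = dplyr::bind_cols(tibble(country_id = seq_len(J)), Z1),
         truth = list(groups = tibble(country_id = seq_len(J), W = W),
                      records = tibble(record_id = seq_len(N), C = C)),
         config = config),
    class = "rmnch_sim")
}

#' Mask indicator cells completely at random or conditional on a covariate
#'
#' Sets a fraction of indicator cells to `NA`. Under `"MCAR"` every cell is
#' masked independently with probability `rate`. Under `"MAR"` the masking
#' probability follows the logistic rule
#' \eqn{\mathrm{logit}(p) = \mathrm{logit}(rate) + z}, where \eqn{z} is the
#' standardized value of `covariate`, so records high on the covariate lose
#' more cells while the marginal rate stays near `rate`.
#'
#' @param data Tibble of unit records.
#' @param rate Fraction of cells to mask, in `[0, 1)`.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param covariate Column name driving MAR missingness.
#' @param seed Integer seed.
#' @param indicators Indicator columns to mask; defaults to the canonical 12
#'   that are present in `data`.
#' @return `data` with masked cells set to `NA`.
#' @export
inject_missing <- function(data, rate, mechanism = c("MCAR", "MAR"),
                           covariate = NULL, seed = 1L,
                           indicators = intersect(rmnch_indicators(), names(data))) {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(rate) || rate < 0 || rate >= 1) abort("`rate` must lie in [0, 1).")
  if (rate == 0) return(data)
  if (!length(indicators)) abort("No indicator columns found to mask.")
  set.seed(as.integer(seed))
  n <- nrow(data)
  p <- if (mechanism == "MCAR") rep(rate, n) else {
    if (is.null(covariate) || !covariate %in% names(data))
      abort("MAR masking needs an existing `covariate` column.")
    z <- as.numeric(data[[covariate]])
    z <- if (sd(z) > 0) (z - mean(z)) / sd(z) else z * 0
    plogis(qlogis(rate) + z)
  }
  for (col in indicators) {
    mask <- runif(n) < p
    data[[col]][mask] <- NA
  }
  data
}
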