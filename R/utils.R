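#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats plogis qlogis qnorm rbinom rgamma rlnorm runif rnorm
#'   binomial coef glm logLik optim pnorm quantile sd setNames vcov weighted.mean
#' @importFrom utils head modifyList
NULL

# Canonical order of the 12 RMNCH service indicators (continuum of care:
# antenatal -> delivery -> postnatal -> immunization/feeding -> family planning).
rmnch_indicators <- function() {
  c("anc", "tetanus", "facility_delivery", "skilled_attendant",
    "pnc_mother", "pnc_newborn", "bcg", "dpt", "polio", "measles",
    "breastfeeding", "family_planning")
}

# log(sum(exp(x))) along rows of a matrix, guarded against -Inf rows.
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(x - m)))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

clamp_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# One documented stream-splitting rule: the master seed seeds R's RNG once,
# and named sub-streams get seeds drawn from it in a fixed order. Every
# stochastic stage receives its own integer seed below 2^31.
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

assert_prob_vector <- function(p, name, tol = 1e-12) {
  if (any(p < 0) || abs(sum(p) - 1) > tol) {
    abort(sprintf("`%s` must be a probability vector summing to 1 (got sum %.15g).",
                  name, sum(p)))
  }
  invisible(p)
}
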