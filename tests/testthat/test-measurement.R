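test_that("log-likelihood matches hand-computed single-record cases", {
  # one record, one indicator, K = M = 1, rho = 0.7, y = 1
  d <- records_from_matrix(matrix(1L, 1, 1))
  p1 <- mlca_params(1, matrix(1, 1, 1), matrix(0.7, 1, 1))
  expect_equal(lca_loglik(d, p1, indicators = "s1"), log(0.7), tolerance = 1e-10)
  # symmetric two-class mixture: 0.5 * 0.9 + 0.5 * 0.1 = 0.5
  p2 <- mlca_params(1, matrix(c(0.5, 0.5), 1), matrix(c(0.9, 0.1), 2, 1))
  expect_equal(lca_loglik(d, p2, indicators = "s1"), log(0.5), tolerance = 1e-10)
})

test_that("identical tau rows collapse the country level", {
  set.seed(4)
  y <- matrix(rbinom(40, 1, 0.5), 20, 2)
  d <- records_from_matrix(y, group = rep(1:4, each = 5))
  tau <- c(0.3, 0.7)
  rho <- matrix(c(0.8, 0.3, 0.4, 0.6), 2, 2)
  p_m1 <- mlca_params(1, matrix(tau, 1), rho)
  for (pi1 in c(0.2, 0.5, 0.9)) {
    p_m2 <- mlca_params(c(pi1, 1 - pi1), rbind(tau, tau), rho)
    expect_equal(lca_loglik(d, p_m2, indicators = c("s1", "s2")),
                 lca_loglik(d, p_m1, indicators = c("s1", "s2")),
                 tolerance = 1e-10)
  }
})

test_that("K = M = 1 reduces to weighted Bernoulli maximum likelihood", {
  set.seed(11)
  y <- matrix(rbinom(60, 1, c(0.3, 0.7, 0.5)), 20, 3, byrow = TRUE)
  w <- runif(20, 0.5, 2)
  d <- records_from_matrix(y, group = rep(1:2, each = 10), weight = w)
  fit <- fit_mlca(d, K = 1, M = 1, n_starts = 2, seed = 1,
                  indicators = c("s1", "s2", "s3"))
  wm <- colSums(w * y) / sum(w)
  expect_equal(unname(fit$params$rho[1, ]), unname(wm), tolerance = 1e-6)
  ll_closed <- sum(vapply(1:3, function(h)
    sum(w * (y[, h] * log(wm[h]) + (1 - y[, h]) * log(1 - wm[h]))), numeric(1)))
  expect_equal(fit$loglik, ll_closed, tolerance = 1e-8)
})

test_that("EM attains the exhaustive grid-search maximum on tiny instances", {
  for (sd in 1:3) {
    set.seed(sd)
    y <- matrix(rbinom(12, 1, 0.5), 6, 2)
    d <- records_from_matrix(y, group = rep(1:2, each = 3))
    fit <- fit_mlca(d, K = 2, M = 1, n_starts = 25, seed = sd,
                    indicators = c("s1", "s2"), tol = 1e-12)
    oracle <- grid_oracle_k2(y)
    expect_gte(fit$loglik, oracle$lattice01 - 1e-4)
    expect_lt(abs(fit$loglik - oracle$refined), 1e-4)
  }
})

test_that("EM log-likelihood is monotone over iterations", {
  cfg <- rmnch_config(J = 10, n_per_group = 80, seed = 17)
  sim <- simulate_rmnch(cfg)
  fit <- fit_mlca(sim$data, K = 2, M = 2, n_starts = 3, seed = 2)
  expect_true(all(diff(fit$ll_trace) > -1e-7 * abs(fit$ll_trace[-1])))
})

test_that("posteriors follow Bayes' rule and normalize", {
  # hand computation: tau = (0.6, 0.4), rho1 = (0.9, 0.8), rho2 = (0.2, 0.3),
  # y = (1,1): P(class 1 | y) = 0.432 / 0.456
  d <- records_from_matrix(matrix(c(1L, 1L), 1, 2))
  p <- mlca_params(1, matrix(c(0.6, 0.4), 1),
                   rbind(c(0.9, 0.8), c(0.2, 0.3)))
  post <- compute_posteriors(d, p, indicators = c("s1", "s2"))
  expect_equal(post$indiv_post[1, 1], 0.432 / 0.456, tolerance = 1e-6)

  cfg <- rmnch_config(J = 8, n_per_group = 50, seed = 23)
  sim <- simulate_rmnch(cfg)
  post2 <- compute_posteriors(sim$data, mlca_params(cfg$pi, cfg$tau, cfg$rho))
  expect_equal(rowSums(post2$indiv_post), rep(1, nrow(sim$data)), tolerance = 1e-8)
  expect_equal(rowSums(post2$group_post), rep(1, cfg$J), tolerance = 1e-8)
  expect_equal(apply(post2$joint_post, 1L, sum), rep(1, nrow(sim$data)),
               tolerance = 1e-8)
})

test_that("indistinguishable classes give uniform posteriors", {
  d <- records_from_matrix(matrix(c(1L, 0L, 1L, 1L), 2, 2), group = c(1L, 2L))
  p <- mlca_params(c(0.5, 0.5), matrix(0.5, 2, 2),
                   rbind(c(0.6, 0.4), c(0.6, 0.4)))
  post <- compute_posteriors(d, p, indicators = c("s1", "s2"))
  expect_equal(unname(post$indiv_post), matrix(0.5, 2, 2), tolerance = 1e-10)
  expect_equal(unname(post$group_post), matrix(0.5, 2, 2), tolerance = 1e-10)
})

test_that("record and group relabeling leave the fit invariant", {
  cfg <- rmnch_config(J = 8, n_per_group = 40, seed = 29)
  sim <- simulate_rmnch(cfg)
  fit1 <- fit_mlca(sim$data, K = 2, M = 2, n_starts = 5, seed = 3)
  set.seed(1)
  shuffled <- sim$data[sample(nrow(sim$data)), ]
  shuffled$country_id <- match(shuffled$country_id, c(5, 3, 8, 1, 7, 2, 6, 4))
  fit2 <- fit_mlca(shuffled, K = 2, M = 2, n_starts = 5, seed = 3)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-6)
  expect_equal(fit1$params$rho, fit2$params$rho, tolerance = 1e-4)
  expect_equal(fit1$params$pi, fit2$params$pi, tolerance = 1e-4)
})

test_that("parameters are recovered from moderate synthetic data", {
  cfg <- rmnch_config(J = 30, n_per_group = 200, seed = 37)
  sim <- simulate_rmnch(cfg)
  fit <- fit_mlca(sim$data, K = 2, M = 2, n_starts = 8, seed = 5)
  expect_true(fit$converged)
  expect_lt(sqrt(mean((fit$params$rho - cfg$rho)^2)), 0.03)
  expect_lt(max(abs(fit$params$tau - cfg$tau)), 0.1)
  truth <- dplyr::left_join(sim$data["record_id"], sim$truth$records, "record_id")
  expect_gt(mean(fit$posteriors$map_indiv == truth$C), 0.9)
  w_true <- sim$truth$groups$W
  expect_gt(mean(fit$posteriors$map_group == w_true), 0.95)
})

test_that("class summaries are normalized and recover the generating shares", {
  cfg <- rmnch_config(J = 30, n_per_group = 200, seed = 41)
  sim <- simulate_rmnch(cfg)
  fit <- fit_mlca(sim$data, K = 2, M = 2, n_starts = 8, seed = 7)
  tabs <- summarize_classes(fit$posteriors)
  expect_equal(sum(tabs$higher$share), 1, tolerance = 1e-8)
  expect_equal(sum(tabs$lower$share), 1, tolerance = 1e-8)
  cond <- tidyr::pivot_wider(tabs$lower_given_higher,
                             names_from = "lower_class", values_from = "share")
  expect_equal(rowSums(as.matrix(cond[, c("optimal", "suboptimal")])),
               c(1, 1), tolerance = 1e-8, ignore_attr = TRUE)
  # conditional optimal shares near the generating tau
  expect_lt(abs(cond$optimal[cond$higher_class == "high_coverage"] - 0.827), 0.05)
  expect_lt(abs(cond$optimal[cond$higher_class == "low_coverage"] - 0.465), 0.07)
  # the population mixture arithmetic: equal-size groups imply an overall
  # optimal share near sum_m pi_m tau_{1|m}
  mix <- sum(cfg$pi * cfg$tau[, 1])
  expect_equal(mix, 0.656 * 0.827 + 0.344 * 0.465, tolerance = 1e-12)
  expect_lt(abs(tabs$lower$share[1] - mix), 0.08)
  expect_equal(nrow(tabs$assignments), 30L)
})

test_that("weights act as frequency weights", {
  set.seed(19)
  y <- matrix(rbinom(30, 1, 0.5), 15, 2)
  base <- records_from_matrix(rbind(y, y[1:5, ]), group = rep(1L, 20))
  wtd <- records_from_matrix(y, group = rep(1L, 15),
                             weight = c(rep(2, 5), rep(1, 10)))
  p <- mlca_params(1, matrix(c(0.4, 0.6), 1), rbind(c(0.8, 0.7), c(0.2, 0.25)))
  expect_equal(lca_loglik(wtd, p, indicators = c("s1", "s2")),
               lca_loglik(base, p, indicators = c("s1", "s2")), tolerance = 1e-9)
})

test_that("requesting excess classes warns and flags the fit", {
  d <- records_from_matrix(matrix(c(1L, 1L, 0L, 0L), 4, 2), group = rep(1:2, 2))
  expect_warning(fit <- fit_mlca(d, K = 3, M = 1, n_starts = 2, seed = 1,
                                 indicators = c("s1", "s2"), max_iter = 50),
                 "boundary")
  expect_true(fit$boundary)
})
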