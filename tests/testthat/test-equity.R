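strat_from_groups <- function(y_by_group, n_each = 100, order = NULL) {
  labs <- names(y_by_group)
  d <- dplyr::bind_rows(lapply(seq_along(labs), function(i)
    tibble::tibble(outcome = y_by_group[[i]], subgroup = labs[i],
                   country_id = rep(1:4, length.out = length(y_by_group[[i]])))))
  stratified_outcome(d, "outcome", "subgroup", order = order)
}

test_that("stratified aggregation produces shares, means and midpoint ranks", {
  s <- strat_from_groups(list(poor = rep(0.4, 100), rich = rep(0.6, 100)),
                         order = c("poor", "rich"))
  expect_equal(s$groups$p, c(0.5, 0.5))
  expect_equal(s$groups$x, c(0.25, 0.75))
  expect_equal(s$mu, 0.5)
  expect_equal(sum(s$groups$p), 1, tolerance = 1e-10)
  expect_equal(sum(s$groups$p * s$groups$y), s$mu, tolerance = 1e-10)
  expect_error(stratified_outcome(tibble::tibble(outcome = 2, subgroup = "a",
                                                 country_id = 1),
                                  "outcome", "subgroup"), "0, 1")
})

test_that("difference and ratio behave under equality, order swap, and subdivision", {
  eq <- strat_from_groups(list(a = rep(0.5, 50), b = rep(0.5, 50)))
  m <- simple_measures(eq, "a", "b")
  expect_equal(m$estimate, c(0, 1))

  s <- strat_from_groups(list(rural = rep(0.62, 80), urban = rep(0.85, 80)))
  m1 <- simple_measures(s, "urban", "rural")
  expect_equal(m1$estimate[m1$measure == "difference"], 0.23, tolerance = 1e-10)
  expect_equal(m1$estimate[m1$measure == "ratio"], 0.85 / 0.62, tolerance = 1e-10)
  m2 <- simple_measures(s, "rural", "urban")
  expect_equal(m2$estimate[1], -m1$estimate[1], tolerance = 1e-12)
  expect_equal(m2$estimate[2], 1 / m1$estimate[2], tolerance = 1e-12)
  # subdividing a group into equal-mean halves changes nothing
  s3 <- strat_from_groups(list(rural = rep(0.62, 80), urban1 = rep(0.85, 40),
                               urban2 = rep(0.85, 40)))
  expect_equal(simple_measures(s3, "urban1", "rural")$estimate, m1$estimate)

  zero <- strat_from_groups(list(a = rep(0, 10), b = rep(0.5, 10)))
  expect_error(simple_measures(zero, "b", "a"), "ratio undefined")
})

test_that("concentration indices match the midpoint-rank formula", {
  flat <- strat_from_groups(list(p = rep(0.3, 30), m = rep(0.3, 30), r = rep(0.3, 30)),
                            order = c("p", "m", "r"))
  expect_equal(concentration_indices(flat)$estimate, c(0, 0), tolerance = 1e-12)
  s <- strat_from_groups(list(poor = rep(0.4, 50), rich = rep(0.6, 50)),
                         order = c("poor", "rich"))
  ci <- concentration_indices(s)
  expect_equal(ci$estimate[ci$measure == "RCI"], 0.10, tolerance = 1e-10)
  expect_equal(ci$estimate[ci$measure == "ACI"], 0.05, tolerance = 1e-10)
  rev <- strat_from_groups(list(poor = rep(0.4, 50), rich = rep(0.6, 50)),
                           order = c("rich", "poor"))
  expect_equal(concentration_indices(rev)$estimate, -ci$estimate, tolerance = 1e-10)
  unord <- strat_from_groups(list(a = rep(0.4, 10), b = rep(0.6, 10)))
  expect_error(concentration_indices(unord), "ordered")
})

test_that("SII/RII reproduce the exact two-point logit solution", {
  s <- strat_from_groups(list(poor = rep(0.4, 50), rich = rep(0.6, 50)),
                         order = c("poor", "rich"))
  out <- sii_rii(s, link = "logit")
  # exact fit through logits at x = 0.25, 0.75: slope 2*logit(0.6)/0.5
  b <- (qlogis(0.6) - qlogis(0.4)) / 0.5
  nu <- plogis(qlogis(0.4) - 0.25 * b + b * c(0, 1))
  expect_equal(out$estimate[out$measure == "SII"], nu[2] - nu[1], tolerance = 1e-6)
  expect_equal(out$estimate[out$measure == "RII"], nu[2] / nu[1], tolerance = 1e-6)
  expect_equal(round(out$estimate, 4), c(0.3846, 2.2500), ignore_attr = TRUE)

  flat <- strat_from_groups(list(a = rep(0.3, 10), b = rep(0.3, 10)),
                            order = c("a", "b"))
  expect_equal(sii_rii(flat, "logit")$estimate, c(0, 1), tolerance = 1e-8)
  expect_equal(sii_rii(flat, "identity")$estimate, c(0, 1), tolerance = 1e-10)
  # logit-link extreme predictions remain inside (0, 1)
  steep <- strat_from_groups(list(a = rep(0.02, 10), b = rep(0.98, 10)),
                             order = c("a", "b"))
  out2 <- sii_rii(steep, "logit")
  expect_lt(out2$estimate[out2$measure == "SII"], 1)
})

test_that("PAR/PAF definitions and identity hold", {
  s <- strat_from_groups(list(a = rep(0.4, 50), b = rep(0.6, 50)))
  out <- par_paf(s)   # best subgroup = 0.6, mu = 0.5
  expect_equal(out$estimate, c(0.1, 20), tolerance = 1e-10)
  expect_equal(out$estimate[2], 100 * out$estimate[1] / s$mu, tolerance = 1e-12)
  ref_self <- par_paf(s, reference = "a")  # below the mean: floored at 0
  expect_equal(ref_self$estimate, c(0, 0))
  expect_error(par_paf(s, reference = "zzz"), "not present")
})

test_that("all measures sit at their null fixed points on constant outcomes", {
  s <- strat_from_groups(list(g1 = rep(0.37, 40), g2 = rep(0.37, 40),
                              g3 = rep(0.37, 40)), order = c("g1", "g2", "g3"))
  expect_equal(simple_measures(s, "g3", "g1")$estimate, c(0, 1), tolerance = 1e-10)
  expect_equal(concentration_indices(s)$estimate, c(0, 0), tolerance = 1e-10)
  expect_equal(sii_rii(s)$estimate, c(0, 1), tolerance = 1e-8)
  expect_equal(par_paf(s)$estimate, c(0, 0), tolerance = 1e-10)
})

test_that("ACI = mu * RCI holds on arbitrary random inputs", {
  set.seed(12)
  for (r in 1:10) {
    ng <- sample(2:5, 1)
    ys <- lapply(seq_len(ng), function(i) runif(sample(20:60, 1)))
    names(ys) <- paste0("g", seq_len(ng))
    s <- strat_from_groups(ys, order = names(ys))
    ci <- concentration_indices(s)
    expect_equal(ci$estimate[ci$measure == "ACI"],
                 s$mu * ci$estimate[ci$measure == "RCI"], tolerance = 1e-12)
    pp <- par_paf(s)
    expect_equal(pp$estimate[2], 100 * pp$estimate[1] / s$mu, tolerance = 1e-10)
  }
})

boot_data <- function(seed = 1, J = 12) {
  set.seed(seed)
  d <- tibble::tibble(
    country_id = rep(seq_len(J), each = 60),
    wealth = sample(c("poor", "middle", "rich"), 60 * J, replace = TRUE))
  country_fx <- rnorm(J, 0, 0.5)
  base <- c(poor = -0.4, middle = 0, rich = 0.5)
  d$outcome <- plogis(base[d$wealth] + country_fx[d$country_id] +
                        rnorm(nrow(d), 0, 0.3))
  d
}

test_that("country-clustered bootstrap is reproducible and sane", {
  d <- boot_data()
  s <- stratified_outcome(d, "outcome", "wealth",
                          order = c("poor", "middle", "rich"))
  ci1 <- cluster_bootstrap_ci(s, "SII", B = 100, seed = 7)
  ci2 <- cluster_bootstrap_ci(s, "SII", B = 100, seed = 7)
  expect_identical(ci1, ci2)
  expect_true(ci1$CI_low <= ci1$estimate && ci1$estimate <= ci1$CI_high)
  ci3 <- cluster_bootstrap_ci(s, "difference", B = 100, seed = 7,
                              advantaged = "rich", disadvantaged = "poor")
  expect_true(ci3$CI_low <= ci3$estimate && ci3$estimate <= ci3$CI_high)
  expect_warning(cluster_bootstrap_ci(s, "RCI", B = 1, seed = 1), "degenerate")
  one <- stratified_outcome(d[d$country_id == 1, ], "outcome", "wealth",
                            order = c("poor", "middle", "rich"))
  expect_error(cluster_bootstrap_ci(one, "RCI", B = 10), "2 countries")
})

test_that("the equity table assembles the measure-by-dimension layout", {
  d <- boot_data(3)
  d$residence <- ifelse(runif(nrow(d)) < 0.4, "urban", "rural")
  tab <- equity_table(
    d, "outcome",
    dimensions = list(
      wealth = list(subgroup = "wealth", order = c("poor", "middle", "rich")),
      residence = list(subgroup = "residence", advantaged = "urban",
                       disadvantaged = "rural")),
    B = 50, seed = 11)
  expect_setequal(tab$measure[tab$dimension == "wealth"],
                  c("difference", "ratio", "ACI", "RCI", "SII", "RII", "PAR", "PAF"))
  expect_setequal(tab$measure[tab$dimension == "residence"],
                  c("difference", "ratio", "PAR", "PAF"))
  expect_true(all(tab$CI_low <= tab$CI_high))
  expect_true(all(tab$estimate[tab$measure %in% c("ratio", "RII")] > 0))
})
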