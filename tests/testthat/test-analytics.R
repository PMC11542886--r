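# Design-space enumeration, pairwise impacts, LHS, KS filtering and the
# grid-map optimizer

test_that("default decision space enumerates to the full factorial count", {
  sc <- enumerate_scenarios(decision_space())
  # independent counting oracle: per reactor type,
  # (stages x extraction options) x temperature x HRT x degassing x beads
  ext <- function(stages) if (stages == 1) 1 else 1 + 2 + 2
  base <- sum(vapply(c(1, 2), ext, 0)) * 2 * 4 * 2    # = 96 per type core
  expect_equal(sum(sc$reactor_type == "UASB"), base)
  expect_equal(sum(sc$reactor_type == "packed_bed"), base * 3 * 3)
  expect_equal(sum(sc$reactor_type == "fluidized_bed"), base * 3 * 3 * 3)
  expect_equal(nrow(sc), base * (1 + 9 + 27))
  expect_equal(nrow(sc), 3552)
  expect_equal(nrow(dplyr::distinct(sc[, -1])), nrow(sc))
  # restriction to UASB only
  expect_equal(nrow(enumerate_scenarios(decision_space(reactor_type = "UASB"))),
               96)
  expect_error(enumerate_scenarios(decision_space(hrt_d = numeric())),
               "empty option set")
})

test_that("enumeration order is deterministic", {
  a <- enumerate_scenarios(decision_space())
  b <- enumerate_scenarios(decision_space())
  expect_identical(a, b)
})

test_that("pairwise deltas: arithmetic, antisymmetry and bounds", {
  # 3-scenario toy with indicator values 1, 2, 4 differing only in hrt_d
  df <- tibble::tibble(reactor_type = "UASB", stages = 1, temperature_c = 22,
                       hrt_d = c(1, 2, 4), degassing = FALSE,
                       y = c(1, 2, 4))
  d <- pairwise_delta(df, "y", "hrt_d", baseline = 1)
  expect_equal(d$delta[d$alternative == "2"], 1 / 3)
  expect_equal(d$delta[d$alternative == "4"], 1)
  # antisymmetry under swapping baseline and alternative
  d2 <- pairwise_delta(df, "y", "hrt_d", baseline = 2)
  expect_equal(d2$delta[d2$alternative == "1"],
               -d$delta[d$alternative == "2"])
  expect_error(pairwise_delta(dplyr::mutate(df, y = 5), "y", "hrt_d", 1),
               "distinct")
  # |delta| <= 1 over a random scenario table
  set.seed(5)
  big <- tidyr::expand_grid(reactor_type = c("a", "b"), hrt_d = c(1, 2, 4),
                            degassing = c(TRUE, FALSE))
  big$y <- rnorm(nrow(big))
  for (v in c("hrt_d", "reactor_type", "degassing")) {
    dd <- pairwise_delta(big, "y", v, baseline = big[[v]][1])
    expect_true(all(abs(dd$delta) <= 1 + 1e-12))
  }
})

test_that("LHS sampling is stratified, bounded and seed-deterministic", {
  ds <- make_parameter_space("fluidized_bed")
  n <- 40
  s1 <- lhs_sample(ds, n, seed = 9)
  s2 <- lhs_sample(ds, n, seed = 9)
  expect_identical(s1, s2)
  expect_false(identical(s1, lhs_sample(ds, n, seed = 10)))
  for (j in seq_len(nrow(ds))) {
    x <- s1[[ds$name[j]]]
    expect_true(all(x >= ds$min[j] & x <= ds$max[j]))
  }
  # exact stratification: for uniform margins each of n strata hit once
  unif <- ds[ds$dist == "uniform", ]
  for (j in seq_len(nrow(unif))) {
    x <- s1[[unif$name[j]]]
    u <- (x - unif$min[j]) / (unif$max[j] - unif$min[j])
    expect_equal(sort(floor(u * n)), 0:(n - 1))
  }
  # single sample lies inside the support
  s_one <- lhs_sample(ds, 1, seed = 1)
  expect_equal(nrow(s_one), 1)
})

test_that("KS statistic equals the brute-force ECDF scan", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  expect_equal(ks_two_sample(a, b)$statistic, 1)
  expect_equal(ks_two_sample(a, a)$statistic, 0)
  set.seed(21)
  for (i in 1:1000) {
    n1 <- sample(2:25, 1); n2 <- sample(2:25, 1)
    x <- rnorm(n1); y <- rnorm(n2, mean = runif(1, -1, 1))
    expect_equal(ks_two_sample(x, y)$statistic, ks_brute(x, y),
                 tolerance = 1e-12)
  }
  expect_error(ks_two_sample(1, 1:5), "at least 2")
})

test_that("Monte Carlo filter splits 25/75 and flags the driving parameter", {
  set.seed(2)
  n <- 1000
  samples <- tibble::tibble(a = runif(n), b = runif(n), c = runif(n))
  y <- samples$a + 0.01 * rnorm(n)       # driven by a alone
  mf <- monte_carlo_filter(samples, y, "higher_better")
  expect_equal(mf$n_desirable[1], 250)
  expect_equal(mf$n_undesirable[1], 750)
  expect_equal(mf$parameter[which.max(mf$statistic)], "a")
  expect_lt(mf$p_value[mf$parameter == "a"], 1e-10)
  # lower_better direction selects the bottom quartile
  mf2 <- monte_carlo_filter(samples, y, "lower_better")
  expect_equal(mf2$n_desirable[1], 250)
  expect_equal(mf2$parameter[which.max(mf2$statistic)], "a")
})

test_that("null inputs are rarely flagged (type-I behavior)", {
  set.seed(31)
  reps <- 100; k <- 5; n <- 1000
  pvals <- unlist(lapply(seq_len(reps), function(r) {
    samples <- tibble::as_tibble(stats::setNames(
      lapply(seq_len(k), function(j) runif(n)), paste0("p", seq_len(k))))
    y <- rnorm(n)
    monte_carlo_filter(samples, y, "higher_better")$p_value
  }))
  frac <- mean(pvals < 0.05)
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)
  # per-parameter: an independent parameter is insignificant >= 90% of runs
  expect_gt(mean(pvals > 0.05), 0.9)
})

test_that("reactor preference filter groups by the paired sign", {
  set.seed(8)
  n <- 400
  samples <- tibble::tibble(hrt = runif(n, 0.2, 5), z = runif(n))
  # preference driven by an HRT threshold
  y_a <- ifelse(samples$hrt > 2, 1, 3) + 0.01 * rnorm(n)
  y_b <- rep(2, n) + 0.01 * rnorm(n)
  pf <- reactor_preference_filter(samples, y_a, y_b, "lower_better")
  expect_equal(pf$parameter[which.max(pf$statistic)], "hrt")
  expect_error(reactor_preference_filter(samples, y_b, y_b + 1,
                                         "lower_better"),
               "degenerate")
  # brute-force grouping oracle on a random toy
  a_better <- y_a < y_b
  expect_equal(pf$statistic[pf$parameter == "hrt"],
               ks_brute(samples$hrt[a_better], samples$hrt[!a_better]),
               tolerance = 1e-12)
})

test_that("grid-map optimizer recovers analytic minimizers on test functions", {
  # convex bowl with known minimum inside the box
  evalfn <- function(par, dv) {
    list(ci = (dv[["x"]] - 0.3 * par$a)^2 + 2 * (dv[["y"]] - 0.6)^2,
         lc = 0, rcod = 0)
  }
  m <- stage3_map(evalfn, param1 = list(name = "a", values = c(1, 2)),
                  param2 = list(name = "b", values = c(0, 1)),
                  dv_bounds = list(x = c(0, 1), y = c(0, 1)),
                  n_starts = 3, seed = 4)
  expect_equal(nrow(m), 4)
  for (i in seq_len(nrow(m))) {
    expect_lt(abs(m$dv_x[i] - 0.3 * m$a[i]), 0.01)
    expect_lt(abs(m$dv_y[i] - 0.6), 0.01)
  }
  expect_true(all(m$converged))
  # monotone objective pushes decision variables to their bounds
  mono <- stage3_map(function(par, dv) list(ci = dv[["x"]] - dv[["y"]]),
                     param1 = list(name = "a", values = 1),
                     param2 = list(name = "b", values = 1),
                     dv_bounds = list(x = c(0, 1), y = c(0, 1)),
                     n_starts = 2, seed = 4)
  expect_lt(mono$dv_x, 0.01)
  expect_gt(mono$dv_y, 0.99)
  # default grid resolution: 12 x 15 = 180 evaluated points
  m180 <- stage3_map(function(par, dv) list(ci = dv[["x"]]^2),
                     param1 = list(name = "a", values = seq(0, 1,
                                                            length.out = 12)),
                     param2 = list(name = "b", values = seq(0, 1,
                                                            length.out = 15)),
                     dv_bounds = list(x = c(0, 1)), n_starts = 1, seed = 1,
                     maxit = 5)
  expect_equal(nrow(m180), 180)
})

test_that("rank correlation helper is Spearman", {
  set.seed(12)
  x <- rnorm(50); y <- 2 * x + rnorm(50)
  expect_equal(indicator_rank_correlation(x, y),
               cor(rank(x), rank(y)), tolerance = 1e-12)
})
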