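paper_temps <- c(2, 10, 20, 30, 37, 45, 53, 60)
paper_salts <- c(0, 0.5, 0.75, 1, 1.5, 2, 3, 4)

test_that("Gaussian fit recovers noiseless model data exactly", {
  v <- gaussian_rate(paper_temps, v_max = 100, t_m = 30, w = 10)
  fit <- fit_gaussian(paper_temps, v)
  expect_equal(fit$v_max, 100, tolerance = 1e-7)
  expect_equal(fit$t_m, 30, tolerance = 1e-7)
  expect_equal(fit$w, 10, tolerance = 1e-7)
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-9)
  # evaluation contract: prediction at t_m equals v_max
  expect_equal(predict(fit, fit$t_m), fit$v_max)
  expect_error(fit_gaussian(c(1, 2, 3), c(1, 2, 1)), "4 distinct")
  expect_error(fit_gaussian(paper_temps, rep(0, 8)), "positive rate")
})

test_that("Gaussian fit is translation-equivariant in temperature", {
  set.seed(21)
  v <- gaussian_rate(paper_temps, 80, 33, 11) + rnorm(8, 0, 2)
  f0 <- fit_gaussian(paper_temps, v)
  f5 <- fit_gaussian(paper_temps + 5, v)
  expect_equal(f5$t_m, f0$t_m + 5, tolerance = 1e-6)
  expect_equal(f5$w, f0$w, tolerance = 1e-6)
  expect_equal(f5$v_max, f0$v_max, tolerance = 1e-6)
})

test_that("Gaussian NLS matches a brute-force grid-search oracle", {
  # profile v_max out: for fixed (t_m, w) the LS-optimal v_max is
  # sum(v*g)/sum(g^2) with g the unit Gaussian
  grid_fit <- function(temps, v, tm_grid, w_grid) {
    best <- c(Inf, NA, NA)
    for (tm in tm_grid) for (ww in w_grid) {
      g <- exp(-(temps - tm)^2 / (2 * ww^2))
      vm <- sum(v * g) / sum(g^2)
      rss <- sum((v - vm * g)^2)
      if (rss < best[1]) best <- c(rss, tm, ww)
    }
    best
  }
  set.seed(33)
  errs <- t(vapply(1:10, function(i) {
    v <- gaussian_rate(paper_temps, 100, 30, 10) + rnorm(8, 0, 5)
    fit <- fit_gaussian(paper_temps, v)
    coarse <- grid_fit(paper_temps, v, seq(20, 40, 0.1), seq(5, 15, 0.1))
    fine <- grid_fit(paper_temps, v,
                     seq(coarse[2] - 0.1, coarse[2] + 0.1, 0.01),
                     seq(coarse[3] - 0.1, coarse[3] + 0.1, 0.01))
    c(abs(fit$t_m - fine[2]), abs(fit$w - fine[3]))
  }, c(1, 2)))
  # NLS optimum and grid optimum agree to within the grid resolution
  expect_lt(median(errs[, 1]), 0.011)
  expect_lt(median(errs[, 2]), 0.011)
})

test_that("FWHM equals 2.355 w and matches half-maximum root finding", {
  expect_equal(fwhm(10), 23.548, tolerance = 5e-5)
  expect_equal(round(fwhm(1) / 1, 3), 2.355)
  v <- gaussian_rate(paper_temps, 90, 33, 12)
  fit <- fit_gaussian(paper_temps, v)
  half <- fit$v_max / 2
  g <- function(tt) gaussian_rate(tt, fit$v_max, fit$t_m, fit$w) - half
  lo <- uniroot(g, c(fit$t_m - 10 * fit$w, fit$t_m), tol = 1e-12)$root
  hi <- uniroot(g, c(fit$t_m, fit$t_m + 10 * fit$w), tol = 1e-12)$root
  expect_equal(hi - lo, fwhm(fit), tolerance = 1e-9)
  expect_error(fwhm(-2), "> 0")
})

test_that("power fit recovers noiseless salt-inhibition data exactly", {
  v <- power_rate(paper_salts, k = 2, a = 1, v0 = 5)
  fit <- fit_power(paper_salts, v)
  expect_equal(fit$k, 2, tolerance = 1e-12)
  expect_equal(fit$a, 1, tolerance = 1e-12)
  expect_equal(fit$v0, 5)
  expect_equal(fit$sa0, 4, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # k = a: complete inhibition at exactly 1% w/v
  v2 <- power_rate(paper_salts, k = 1.5, a = 1.5, v0 = 3)
  expect_equal(fit_power(paper_salts, v2)$sa0, 1, tolerance = 1e-12)
})

test_that("salt thresholds agree with numeric root finding", {
  k <- 3; a <- 1.5; v0 <- 6
  v <- power_rate(paper_salts, k, a, v0)
  fit <- fit_power(paper_salts, v)
  expect_equal(fit$sai, (3 / 7.5)^2, tolerance = 1e-12)
  expect_equal(fit$sai, 0.16, tolerance = 1e-12)
  # SAI solves k c^-0.5 - a = v0; SA0 solves k c^-0.5 - a = 0
  root_sai <- uniroot(function(cc) k / sqrt(cc) - a - v0, c(1e-6, 100),
                      tol = 1e-14)$root
  root_sa0 <- uniroot(function(cc) k / sqrt(cc) - a, c(1e-6, 100),
                      tol = 1e-14)$root
  expect_equal(fit$sai, root_sai, tolerance = 1e-9)
  expect_equal(fit$sa0, root_sa0, tolerance = 1e-9)
  expect_lt(fit$sai, fit$sa0)
})

test_that("power fit flags a missing inhibition signal", {
  v <- c(5, 1, 1.5, 2, 2.5, 3, 3.5, 4)  # increasing with c: k < 0
  fit <- fit_power(paper_salts, v)
  expect_true(fit$flagged)
  expect_true(is.na(fit$sai) && is.na(fit$sa0))
  expect_error(fit_power(c(0, 1, 2), c(5, 3, 2)), "3 distinct positive")
  expect_error(fit_power(paper_salts[-1], power_rate(paper_salts[-1], 2, 1, 5)),
               "c = 0 observation")
})

test_that("normalization rescales to percent of maximum", {
  expect_equal(normalize_rates(c(10, 20, 40, 20)), c(25, 50, 100, 50))
  expect_equal(normalize_rates(rep(3, 5)), rep(100, 5))
  expect_error(normalize_rates(c(0, 0)), "> 0")
})

test_that("normalization leaves operating-range parameters unchanged", {
  v <- gaussian_rate(paper_temps, 70, 31, 9.5)
  f_raw <- fit_gaussian(paper_temps, v)
  f_nrm <- fit_gaussian(paper_temps, normalize_rates(v))
  expect_equal(f_nrm$t_m, f_raw$t_m, tolerance = 1e-7)
  expect_equal(f_nrm$w, f_raw$w, tolerance = 1e-7)

  vs <- power_rate(paper_salts, 2.2, 0.9, 6)
  s_raw <- fit_power(paper_salts, vs)
  s_nrm <- fit_power(paper_salts, normalize_rates(vs))
  expect_equal(s_nrm$sai, s_raw$sai, tolerance = 1e-9)
  expect_equal(s_nrm$sa0, s_raw$sa0, tolerance = 1e-9)
})

test_that("SA0 increases with k at fixed a, and SAI < SA0 when v0 > 0", {
  # k chosen so complete inhibition falls inside the tested gradient
  for (k in c(1, 2, 4)) {
    fits <- vapply(c(k, k * 1.5), function(kk) {
      fit_power(paper_salts, power_rate(paper_salts, kk, 1, 5))$sa0
    }, 1)
    expect_lt(fits[1], fits[2])
    f <- fit_power(paper_salts, power_rate(paper_salts, k, 1, 5))
    expect_lt(f$sai, f$sa0)
  }
})

test_that("parameter comparison produces Tukey letters at alpha", {
  # identically distributed groups share one letter
  same <- compare_parameters(rep(c(1, 2, 3), 3),
                             rep(c("A", "B", "C"), each = 3), alpha = 0.1)
  expect_true(all(same$summary$letters == "a"))

  # well-separated groups get distinct letters
  two <- compare_parameters(c(0, 0.1, -0.1, 10, 10.1, 9.9),
                            rep(c("lo", "hi"), each = 3), alpha = 0.1)
  expect_length(unique(two$summary$letters), 2L)

  # one group shifted by 10 SDs is alone in its letter
  set.seed(8)
  vals <- c(rnorm(3, 0, 1), rnorm(3, 0, 1), rnorm(3, 0, 1), rnorm(3, 10, 1))
  grp <- rep(c("A", "B", "C", "J"), each = 3)
  cmp <- compare_parameters(vals, grp, alpha = 0.1)
  lj <- cmp$summary$letters[cmp$summary$group == "J"]
  others <- cmp$summary$letters[cmp$summary$group != "J"]
  expect_false(any(grepl(lj, others, fixed = TRUE)))

  expect_error(compare_parameters(rep(1, 6), rep(c("A", "B"), each = 3)),
               "zero within-group variance")
  expect_error(compare_parameters(1:3, c("A", "A", "B")), "2 replicates")
})

test_that("Tukey p-values match the studentized-range closed form", {
  set.seed(13)
  vals <- c(rnorm(3, 0), rnorm(3, 1.2), rnorm(3, 5))
  grp <- rep(c("A", "B", "C"), each = 3)
  cmp <- compare_parameters(vals, grp, alpha = 0.1)
  mse <- sum(unlist(lapply(split(vals, grp), function(x) {
    sum((x - mean(x))^2)
  }))) / (9 - 3)
  means <- vapply(split(vals, grp), mean, 1)
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    q <- abs(means[pair[1]] - means[pair[2]]) / sqrt(mse / 3)
    p_hand <- unname(1 - ptukey(q, nmeans = 3, df = 6))
    expect_equal(cmp$tukey[pair[1], pair[2]], p_hand, tolerance = 1e-10)
  }
  # letter-display invariant: groups sharing a letter have p >= alpha
  for (i in 1:2) for (j in seq(i + 1, 3)) {
    li <- strsplit(cmp$summary$letters[i], "")[[1]]
    lj <- strsplit(cmp$summary$letters[j], "")[[1]]
    if (length(intersect(li, lj)) > 0) {
      expect_gte(cmp$tukey[cmp$summary$group[i], cmp$summary$group[j]],
                 cmp$alpha)
    }
  }
})
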