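test_that("unweighted UniFrac matches hand-enumerated branch fractions", {
  b4 <- balanced4()
  expect_equal(unweighted_unifrac(b4, c("t1", "t2"), c("t1", "t2")), 0)
  expect_equal(unweighted_unifrac(b4, c("t1", "t2"), c("t1", "t3")), 0.6)
  st <- star_tree(6)
  expect_equal(unweighted_unifrac(st, c("t1", "t2"), c("t3", "t4")), 1)
  expect_error(unweighted_unifrac(b4, "t1", character(0)), "non-empty")
  expect_error(unweighted_unifrac(b4, "t1", "zz"), "not in tree")
})

test_that("UniFrac equals the brute-force path-union oracle", {
  set.seed(51)
  tr <- gen_phylogeny(5, seed = 14, jitter_sd = 0.3)
  tips <- tr$tip.label
  subsets <- unlist(lapply(1:5, function(k) {
    combn(tips, k, simplify = FALSE)
  }), recursive = FALSE)
  for (i in seq(1, length(subsets), by = 3)) {
    for (j in seq(2, length(subsets), by = 7)) {
      expect_equal(
        unweighted_unifrac(tr, subsets[[i]], subsets[[j]]),
        unifrac_bruteforce(tr, subsets[[i]], subsets[[j]]),
        tolerance = 1e-12)
    }
  }
})

test_that("UniFrac matrices are symmetric with zero diagonal", {
  tr <- gen_phylogeny(20, seed = 4)
  com <- gen_communities(tr, 4, 3, overlap = 0.5, evenness_sigma = 1,
                         clones_per_library = 50, community_sizes = 8,
                         seed = 5)
  uf <- unifrac_matrix(tr, com$counts)
  expect_equal(dim(uf), c(12L, 12L))
  expect_equal(uf, t(uf))
  expect_true(all(diag(uf) == 0))
  expect_true(all(uf >= 0 & uf <= 1))
  # duplicated composition: off-diagonal zero
  sets <- list(u1 = c("g1", "g2"), u2 = c("g1", "g2"), u3 = c("g3", "g4"))
  uf2 <- unifrac_matrix(tr, sets)
  expect_equal(uf2["u1", "u2"], 0)
  expect_error(unifrac_matrix(tr, list(u1 = "g1", u2 = character(0))),
               "empty unit")
})

test_that("AMOVA partitions variance as the sums-of-squares oracle", {
  # two maximally distinct groups: all within 0, all between 1
  d <- matrix(1, 6, 6) - diag(6)
  d[1:3, 1:3] <- 0; d[4:6, 4:6] <- 0
  rownames(d) <- colnames(d) <- paste0("u", 1:6)
  grp <- setNames(rep(c("A", "B"), each = 3), rownames(d))
  res <- amova(d, grp, permutations = 99, seed = 1)
  expect_equal(res$percent_among, 100)
  expect_equal(res$phi_st, 1)
  # hand-computed SS partition: SS_total = 9/6 * ... sum d^2 lower = 9
  expect_equal(unname(res$ss["total"]), 9 / 6 * 1)
  expect_equal(unname(res$ss["within"]), 0)

  # identical composition across groups: phi ~ 0, p ~ 1
  set.seed(3)
  pts <- rnorm(20)
  d2 <- as.matrix(dist(c(pts, pts)))
  rownames(d2) <- colnames(d2) <- paste0("u", 1:40)
  grp2 <- setNames(rep(c("A", "B"), each = 20), rownames(d2))
  # groups have literally identical internal structure
  res2 <- amova(d2, grp2, permutations = 999, seed = 7)
  expect_lt(abs(res2$phi_st), 0.1)
  expect_gt(res2$p_value, 0.3)
  expect_equal(res2$percent_among + res2$percent_within, 100)

  # determinism
  res3 <- amova(d2, grp2, permutations = 999, seed = 7)
  expect_identical(res2$p_value, res3$p_value)
  expect_error(amova(d, setNames(c("A", "A", "A", "A", "A", "B"),
                                 rownames(d)), 99), ">= 2 groups")
})

test_that("AMOVA percent-among grows as community overlap shrinks", {
  pct <- vapply(c(1, 0.5, 0), function(ov) {
    tr <- gen_phylogeny(60, seed = 21)
    com <- gen_communities(tr, 3, 2, overlap = ov, evenness_sigma = 0.5,
                           clones_per_library = 40, community_sizes = 15,
                           seed = 22)
    geno <- com$mapping$genotype
    d <- outer(geno, geno, FUN = "!=") * 1
    amova(d, setNames(com$mapping$community, NULL),
          permutations = 49, seed = 5)$percent_among
  }, 1)
  expect_true(all(diff(pct) > 0))
})

test_that("NMDS recovers a true 2-D configuration with near-zero stress", {
  set.seed(61)
  pts <- matrix(rnorm(24), 12, 2)
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("u", 1:12)
  ord <- nmds(d, dims = 2, n_starts = 20, seed = 3)
  expect_lt(ord$stress, 0.01)
  expect_equal(unname(colMeans(ord$points)), c(0, 0), tolerance = 1e-8)
  # stress is invariant to rotation/reflection of the configuration
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  s0 <- kruskal_stress(d, ord$points)
  expect_equal(kruskal_stress(d, ord$points %*% rot), s0, tolerance = 1e-12)
  expect_equal(kruskal_stress(d, ord$points %*% diag(c(-1, 1))), s0,
               tolerance = 1e-12)
  expect_error(nmds(matrix(c(0, NA, NA, 0), 2, 2)), "non-finite|units")
})

test_that("reported stress matches an independent isotonic-regression oracle", {
  set.seed(62)
  # non-metric 4-point dissimilarities
  d <- matrix(0, 4, 4)
  d[lower.tri(d)] <- c(1, 4, 2, 3, 5, 2.5)
  d <- d + t(d)
  rownames(d) <- colnames(d) <- paste0("u", 1:4)
  ord <- nmds(d, dims = 2, n_starts = 20, seed = 9)
  expect_equal(ord$stress, stress_oracle(d, ord$points), tolerance = 1e-6)
  # and on a larger random matrix
  d2 <- as.matrix(dist(matrix(rnorm(16), 8, 2))) + runif(1)
  diag(d2) <- 0
  ord2 <- nmds(d2, dims = 2, n_starts = 20, seed = 10)
  expect_equal(ord2$stress, stress_oracle(d2, ord2$points), tolerance = 1e-6)
})

test_that("vector fitting recovers axis-aligned variables exactly", {
  set.seed(71)
  pts <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("u", 1:10),
                                                  c("NMDS1", "NMDS2")))
  v <- pts[, 1]
  fv <- fit_env_vector(pts, v, permutations = 199, seed = 1)
  expect_equal(fv$r_squared, 1, tolerance = 1e-10)
  expect_equal(abs(unname(fv$direction)), c(1, 0), tolerance = 1e-8)
  expect_error(fit_env_vector(pts, rep(1, 10)), "constant")
  # independent variable: r2 near 0 on average, p not extreme
  v2 <- rnorm(10)
  fv2 <- fit_env_vector(pts, v2, permutations = 999, seed = 2)
  expect_gt(fv2$p_value, 0.001)
})

test_that("exact vector-fitting p-values match full enumeration", {
  set.seed(72)
  pts <- matrix(rnorm(10), 5, 2)
  v <- rnorm(5)
  fv <- fit_env_vector(pts, v, exact = TRUE)
  # independent lexicographic enumeration
  x <- scale(pts, center = TRUE, scale = FALSE)
  r2_fun <- function(vv) {
    vv <- vv - mean(vv)
    pred <- x %*% qr.solve(crossprod(x), crossprod(x, vv))
    sum(pred^2) / sum(vv^2)
  }
  perms <- lex_permutations(5)
  r2_all <- apply(perms, 1, function(ix) r2_fun(v[ix]))
  p_oracle <- sum(r2_all >= fv$r_squared - 1e-12) / nrow(perms)
  expect_equal(fv$permutations, 120L)
  expect_equal(fv$p_value, p_oracle)
})

test_that("Mantel statistic and exact p match enumeration", {
  set.seed(81)
  d1 <- as.matrix(dist(rnorm(4)))
  expect_equal(mantel_test(d1, 2 * d1, permutations = 99, seed = 1)$r, 1)
  d2 <- as.matrix(dist(rnorm(4)))
  mt <- mantel_test(d1, d2, exact = TRUE)
  perms <- lex_permutations(4)
  lt <- lower.tri(d1)
  r_all <- apply(perms, 1, function(ix) cor(d1[lt], d2[ix, ix][lt]))
  p_oracle <- sum(r_all >= mt$r - 1e-12) / nrow(perms)
  expect_equal(mt$p_value, p_oracle)
  expect_equal(mt$permutations, 24L)
  # seeded reproducibility
  m1 <- mantel_test(d1, d2, permutations = 999, seed = 5)
  m2 <- mantel_test(d1, d2, permutations = 999, seed = 5)
  expect_identical(m1, m2)
  expect_error(mantel_test(d1, as.matrix(dist(rnorm(5)))), "mismatch")
})

test_that("Mantel and vector fitting agree with vegan", {
  skip_if_not_installed("vegan")
  set.seed(82)
  d1 <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  d2 <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  expect_equal(mantel_test(d1, d2, permutations = 99, seed = 1)$r,
               unname(vegan::mantel(d1, d2, permutations = 99)$statistic),
               tolerance = 1e-10)
  pts <- matrix(rnorm(20), 10, 2)
  v <- rnorm(10)
  fv <- fit_env_vector(pts, v, permutations = 99, seed = 1)
  ef <- vegan::envfit(pts, data.frame(v = v), permutations = 99)
  expect_equal(fv$r_squared, unname(ef$vectors$r), tolerance = 1e-10)
  expect_equal(abs(unname(fv$direction)),
               abs(as.numeric(ef$vectors$arrows)), tolerance = 1e-6)
})

test_that("pairwise correlations match cor.test", {
  x <- c(1, 2, 3, 4, 5)
  tab <- data.frame(x = x, y = 3 * x, z = c(2, 1, 4, 3, 6))
  pc <- pairwise_correlations(tab)
  expect_equal(pc$r_squared[pc$var1 == "x" & pc$var2 == "y"], 1,
               tolerance = 1e-12)
  ct <- cor.test(x, tab$z)
  row <- pc[pc$var1 == "x" & pc$var2 == "z", ]
  expect_equal(row$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(row$p_value, ct$p.value, tolerance = 1e-12)
  expect_error(pairwise_correlations(data.frame(a = 1:5, b = rep(2, 5))),
               "constant")
})

test_that("permutation p-values are super-uniform under the null", {
  set.seed(91)
  ps <- vapply(1:40, function(i) {
    d1 <- as.matrix(dist(rnorm(8)))
    d2 <- as.matrix(dist(rnorm(8)))
    mantel_test(d1, d2, permutations = 99, seed = i)$p_value
  }, 1)
  # under the null, P(p <= 0.05) <= ~0.05; allow binomial slack
  expect_lte(mean(ps <= 0.05), 0.15)
})
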