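comparator_fixture <- function(n = 150, seed = 70) {
  g <- simulate_genotypes(n, fixture_panel(), seed = seed)
  set.seed(seed + 1)
  ph <- ge_pheno(data.frame(y = rnorm(n), e = rnorm(n)), trait = "y", env = "e")
  list(g = g, ph = ph, r = residualize(ph, g),
       part = classify_variants(g))
}

test_that("WSS statistic is the squared Madsen-Browning-weighted score", {
  f <- comparator_fixture()
  res <- wss_ge_test(f$r, f$g, B = 99, seed = 2)
  q <- f$g$maf[f$r$kept_idx]
  a <- 1 / sqrt(f$r$n * q * (1 - q))
  uv <- oracle_UV(f$r$y_res, f$r$S_res)
  expect_equal(res$statistic, sum(a * uv$U)^2, tolerance = 1e-10)

  # equal MAFs: the weighted sum is proportional to the plain row sum, and
  # the p-value matches the unweighted burden (ranks unaffected by scale)
  set.seed(9)
  dos <- matrix(rbinom(100 * 3, 2, 0.1), 100, 3)
  dos[1, ] <- pmax(dos[1, ], c(1, 1, 1))  # keep columns polymorphic
  g2 <- ge_genotypes(dos)
  g2$maf <- rep(0.1, 3)  # force exactly equal weights
  r2 <- make_resid(rnorm(100), matrix(rnorm(300), 100, 3))
  res_w <- wss_ge_test(r2, g2, B = 199, seed = 5)
  burden <- permutation_pvalue(r2, statistic = function(U, V) sum(U)^2,
                               B = 199, seed = 5)
  expect_equal(res_w$p_value, burden$p_value)
})

test_that("opposite-direction effects cancel in WSS but not in TOW-GE", {
  set.seed(71)
  n <- 120
  y <- rnorm(n)
  s1 <- y + 0.3 * rnorm(n)
  s2 <- -y + 0.3 * rnorm(n)
  r <- make_resid(y, cbind(s1, s2))
  g <- ge_genotypes(matrix(rbinom(n * 2, 2, 0.1), n, 2))
  uv <- oracle_UV(y, cbind(s1, s2))
  expect_true(all(abs(uv$U) > 10))           # strong per-column signal
  res_w <- wss_ge_test(r, g, B = 299, seed = 3)
  res_t <- tow_ge_test(r, B = 299, seed = 3)
  # aggregation cancels: the burden statistic is orders of magnitude below
  # the direction-robust TOW statistic, and only TOW detects the signal
  expect_lt(res_w$statistic, 0.01 * sum(uv$U^2))
  expect_gt(res_t$statistic, 0.5 * sum(uv$U^2 / uv$V))
  expect_lt(res_t$p_value, res_w$p_value)
})

test_that("WSS is invariant to variant relabelling", {
  f <- comparator_fixture(seed = 72)
  res <- wss_ge_test(f$r, f$g, B = 99, seed = 1)
  ord <- rev(seq_along(f$g$maf))
  g2 <- towge:::subset_variants(f$g, ord)
  r2 <- f$r
  r2$S_res <- f$r$S_res[, ord]
  r2$kept_idx <- seq_along(ord)
  g2$maf <- f$g$maf[ord]
  res2 <- wss_ge_test(r2, g2, B = 99, seed = 1)
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-10)
  expect_equal(res2$p_value, res$p_value)
})

test_that("CMC collapses rare carriers and keeps common columns", {
  f <- comparator_fixture(seed = 73)
  res <- cmc_ge_test(f$r, f$part, f$g, f$ph$E, B = 99, seed = 4)
  expect_equal(res$notes$design_cols[1], "rare_collapse")
  expect_length(res$notes$design_cols, 1 + length(f$part$common_idx))
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("CMC with no rare carriers runs on common interactions only", {
  n <- 80
  set.seed(74)
  dos <- cbind(r1 = rep(0, n), c1 = rbinom(n, 2, 0.3))
  dos[1, 1] <- 0  # rare variant monomorphic: no carriers
  g <- ge_genotypes(dos)
  ph <- ge_pheno(data.frame(y = rnorm(n), e = rnorm(n)), trait = "y", env = "e")
  # the monomorphic rare variant's interaction column is dropped upstream
  expect_warning(r <- residualize(ph, g), "degenerate")
  part <- classify_variants(g)
  expect_warning(res <- cmc_ge_test(r, part, g, ph$E, B = 99, seed = 1),
                 "degenerate|carriers")
  expect_equal(res$notes$design_cols, "c1")

  # one common column: the statistic is the squared standardized score
  keep <- which(r$kept_idx == 2L)
  r_c <- make_resid(r$y_res, r$S_res[, keep, drop = FALSE])
  expect_equal(res$statistic, score_statistic(r_c, 1), tolerance = 1e-10)
})

test_that("CMC statistic is invariant to invertible recombination of
           common columns", {
  set.seed(75)
  n <- 100
  y <- rnorm(n)
  C <- matrix(rnorm(n * 2), n, 2)
  part <- structure(list(rare_idx = integer(0), common_idx = 1:2,
                         threshold = 0.05), class = "ge_partition")
  g <- ge_genotypes(matrix(rbinom(n * 2, 2, 0.3), n, 2))
  A <- matrix(c(2, 1, -1, 0.5), 2, 2)  # invertible
  r1 <- make_resid(y, C)
  r2 <- make_resid(y, C %*% A)
  res1 <- cmc_ge_test(r1, part, g, rnorm(n), B = 49, seed = 6)
  res2 <- cmc_ge_test(r2, part, g, rnorm(n), B = 49, seed = 6)
  expect_equal(res1$statistic, res2$statistic, tolerance = 1e-8)
})

test_that("comparator p-values are valid (uniform or conservative) under
           the permutation null", {
  set.seed(950)
  n <- 60
  reps <- 400
  g <- simulate_genotypes(n, fixture_panel(), seed = 76)
  part <- classify_variants(g)
  p_w <- p_c <- numeric(reps)
  for (i in seq_len(reps)) {
    ph <- ge_pheno(data.frame(y = rnorm(n), e = rnorm(n)), trait = "y", env = "e")
    r <- suppressWarnings(residualize(ph, g))
    p_w[i] <- wss_ge_test(r, g, B = 100, seed = i, keep_perms = FALSE)$p_value
    p_c[i] <- suppressWarnings(
      cmc_ge_test(r, part, g, ph$E, B = 100, seed = i, keep_perms = FALSE)$p_value
    )
  }
  ks <- suppressWarnings(ks.test(p_w, "punif"))
  expect_gt(ks$p.value, 0.01)
  # conservative-or-calibrated: rejection rate must not exceed nominal
  mcse <- sqrt(0.05 * 0.95 / reps)
  expect_lte(mean(p_c <= 0.05), 0.05 + 3 * mcse)
  expect_lte(mean(p_w <= 0.05), 0.05 + 3 * mcse)
})
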