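vw_fixture <- function(n = 200, seed = 40) {
  g <- simulate_genotypes(n, fixture_panel(), seed = seed)
  set.seed(seed + 1)
  ph <- ge_pheno(data.frame(y = rnorm(n), x = rnorm(n), e = rnorm(n)),
                 trait = "y", covariates = "x", env = "e")
  part <- classify_variants(g)
  list(r = suppressWarnings(residualize(ph, g)), part = part, g = g)
}

test_that("rare/common split shares the trait and respects the partition", {
  set.seed(1)
  g <- simulate_genotypes(400, c(rep(0.03, 8), 0.2, 0.4), seed = 2)
  ph <- ge_pheno(data.frame(y = rnorm(400), e = rnorm(400)),
                 trait = "y", env = "e")
  r <- residualize(ph, g)
  part <- classify_variants(g)
  expect_length(part$rare_idx, 8)
  expect_length(part$common_idx, 2)
  sides <- split_by_partition(r, part)
  expect_equal(dim(sides$rare$S_res), c(400L, 8L))
  expect_equal(dim(sides$common$S_res), c(400L, 2L))
  expect_identical(sides$rare$y_res, r$y_res)
  expect_identical(sides$common$y_res, r$y_res)

  # empty side -> directed error
  all_rare <- classify_variants(g, threshold = 0.5)
  expect_error(split_by_partition(r, all_rare), "tow_ge_test")
})

test_that("t_lambda is the variance-standardized mixture, exactly as printed", {
  expect_equal(t_lambda(2, 3, 4, 1, 0.5), 1.75)  # 0.25 + 1.5
  expect_equal(t_lambda(2, 3, 4, 1, 1), 2 / 4)
  expect_equal(t_lambda(2, 3, 4, 1, 0), 3 / 1)
  expect_error(t_lambda(1, 1, 0, 1, 0.5))
})

test_that("the nested min-p procedure matches a literal brute-force oracle", {
  set.seed(60)
  n <- 8
  y <- rnorm(n)
  S_rare <- matrix(rnorm(n * 2), n, 2)
  S_common <- matrix(rnorm(n * 1), n, 1)
  r <- make_resid(y, cbind(S_rare, S_common))
  part <- structure(list(rare_idx = 1:2, common_idx = 3L, threshold = 0.05),
                    class = "ge_partition")
  B <- 300; K <- 5; seed <- 17
  res <- vw_tow_ge_test(r, part, B = B, K = K, seed = seed, convention = "raw")
  perms <- replay_perms(n, B, seed)
  p_oracle <- oracle_vw(y, S_rare, S_common, perms, K)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
})

test_that("min-p cannot increase under grid refinement on shared ensembles", {
  f <- vw_fixture()
  res1 <- vw_tow_ge_test(f$r, f$part, B = 200, K = 1, seed = 3)
  res10 <- vw_tow_ge_test(f$r, f$part, B = 200, K = 10, seed = 3)
  # K = 1 grid {0, 1} is a subset of the K = 10 grid, same permutations
  expect_lte(res10$statistic, res1$statistic)
})

test_that("both sides must be driven by one shared permutation stream", {
  f <- vw_fixture(seed = 41)
  B <- 150; K <- 4; seed <- 23
  res <- vw_tow_ge_test(f$r, f$part, B = B, K = K, seed = seed,
                        convention = "raw")
  sides <- split_by_partition(f$r, f$part)
  n <- f$r$n
  shared <- replay_perms(n, B, seed)
  set.seed(seed + 1000)
  indep <- vapply(seq_len(B), function(b) sample.int(n), integer(n))

  nested_minp <- function(perms_r, perms_c) {
    T_r <- c(oracle_tow(f$r$y_res, sides$rare$S_res),
             vapply(seq_len(B), function(b)
               oracle_tow(f$r$y_res[perms_r[, b]], sides$rare$S_res), numeric(1)))
    T_c <- c(oracle_tow(f$r$y_res, sides$common$S_res),
             vapply(seq_len(B), function(b)
               oracle_tow(f$r$y_res[perms_c[, b]], sides$common$S_res), numeric(1)))
    lambdas <- (0:K) / K
    p_lam <- sapply(seq_len(B + 1), function(b) {
      vapply(lambdas, function(l) {
        Tl <- l * T_r / var(T_r) + (1 - l) * T_c / var(T_c)
        sum(Tl > Tl[b]) / B
      }, numeric(1))
    })
    apply(p_lam, 2, min)
  }

  p_min_shared <- nested_minp(shared, shared)
  p_min_indep <- nested_minp(shared, indep)
  # the package reproduces the shared-stream ensemble...
  expect_equal(res$perm_stats, p_min_shared[-1], tolerance = 1e-12)
  # ...and breaking the T_r/T_c dependence changes the ensemble
  expect_false(isTRUE(all.equal(p_min_shared[-1], p_min_indep[-1])))
})

test_that("VW p-values are approximately uniform under the null", {
  set.seed(900)
  n <- 40
  S <- matrix(rnorm(n * 4), n, 4)
  part <- structure(list(rare_idx = 1:2, common_idx = 3:4, threshold = 0.05),
                    class = "ge_partition")
  pvals <- vapply(1:500, function(i) {
    vw_tow_ge_test(make_resid(rnorm(n), S), part, B = 100, K = 5, seed = i,
                   keep_perms = FALSE)$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("VW records lambda_star and side diagnostics", {
  f <- vw_fixture(seed = 44)
  res <- vw_tow_ge_test(f$r, f$part, B = 100, seed = 5)
  expect_true(res$notes$lambda_star >= 0 && res$notes$lambda_star <= 1)
  expect_gt(res$notes$var_r, 0)
  expect_gt(res$notes$var_c, 0)
  expect_equal(glance(res)$lambda_star, res$notes$lambda_star)
})
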