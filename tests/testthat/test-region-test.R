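region_fixture_files <- function(dir, n = 120, seed = 90) {
  g <- simulate_genotypes(n, fixture_panel(), seed = seed)
  rownames(g$dosages) <- paste0("ind", seq_len(n))
  set.seed(seed + 1)
  pheno <- data.frame(
    id = paste0("ind", seq_len(n)),
    bmi = rnorm(n), age = rnorm(n, 50, 8), expo = rnorm(n)
  )
  geno_path <- file.path(dir, "region.tsv")
  pheno_path <- file.path(dir, "pheno.tsv")
  write_dosage_table(g, geno_path)
  readr::write_tsv(pheno, pheno_path, progress = FALSE)
  list(geno = geno_path, pheno = pheno_path, g = g, df = pheno)
}

test_that("file-level runs are deterministic and equal library-level calls", {
  dir <- withr::local_tempdir()
  f <- region_fixture_files(dir)
  cfg <- list(genotypes = f$geno, pheno = f$pheno, trait = "bmi",
              covariates = "age", env = "expo", sample_col = "id",
              methods = c("tow", "vw", "wss", "cmc"),
              B = 500L, seed = 42L, min_maf = 0)
  res1 <- run_region_test(cfg)
  res2 <- run_region_test(cfg)
  expect_identical(res1, res2)

  # library-level call on the in-memory objects agrees up to TSV round-trip
  lib <- ge_region_test(f$df, f$g, trait = "bmi", covariates = "age",
                        env = "expo", methods = c("tow", "vw", "wss", "cmc"),
                        sample_col = "id", B = 500L, seed = 42L, min_maf = 0)
  expect_equal(res1, lib, tolerance = 1e-8)
  expect_identical(res1$p_value, lib$p_value)

  expect_named(res1, c("method", "statistic", "p_value", "n_perm", "seed",
                       "n", "n_variants", "n_rare", "n_common", "n_retained",
                       "n_dropped", "lambda_star", "note"))
  expect_equal(res1$method, c("TOW-GE", "VW-TOW-GE", "WSS-GE", "CMC-GE"))
  expect_true(all(res1$p_value >= 1 / 501 & res1$p_value <= 1))
  expect_equal(res1$n_rare[1], 4)
  expect_equal(res1$n_common[1], 2)

  out_path <- file.path(dir, "res.tsv")
  run_region_test(c(cfg, list(out = out_path)))
  expect_equal(readr::read_tsv(out_path, show_col_types = FALSE)$p_value,
               res1$p_value)
})

test_that("null-region p-values are seed-stable within Monte-Carlo error", {
  dir <- withr::local_tempdir()
  f <- region_fixture_files(dir, seed = 91)
  run_seed <- function(s) {
    ge_region_test(f$df, f$g, trait = "bmi", covariates = "age", env = "expo",
                   methods = "tow", sample_col = "id", B = 2000L, seed = s,
                   min_maf = 0)$p_value
  }
  p1 <- run_seed(1); p2 <- run_seed(2)
  p_bar <- (p1 + p2) / 2
  mcse <- sqrt(p_bar * (1 - p_bar) / 2000)
  expect_lt(abs(p1 - p2), 3 * mcse * sqrt(2))
})

test_that("sample matching and fallbacks behave as specified", {
  dir <- withr::local_tempdir()
  f <- region_fixture_files(dir, seed = 92)

  # empty sample intersection is an error
  df_bad <- f$df
  df_bad$id <- paste0("other", seq_len(nrow(df_bad)))
  expect_error(
    ge_region_test(df_bad, f$g, trait = "bmi", covariates = "age",
                   env = "expo", methods = "tow", sample_col = "id", B = 10),
    "no samples shared"
  )

  # vw on an all-common region falls back to TOW-GE with a warning
  g_common <- towge:::subset_variants(f$g, 5:6)
  expect_warning(
    res <- ge_region_test(f$df, g_common, trait = "bmi", covariates = "age",
                          env = "expo", methods = "vw", sample_col = "id",
                          B = 99, seed = 1),
    "fell back"
  )
  expect_equal(res$method, "TOW-GE")
  expect_match(res$note, "fell back")

  # extreme-rare filter removes sub-threshold variants
  res_f <- ge_region_test(f$df, f$g, trait = "bmi", covariates = "age",
                          env = "expo", methods = "tow", sample_col = "id",
                          B = 99, seed = 1, min_maf = 0.05)
  expect_equal(res_f$n_variants, 2)

  # missing config fields surface as errors
  expect_error(run_region_test(list(genotypes = "x")), "missing")
})

test_that("the bundled synthetic example region runs end to end", {
  vcf <- system.file("extdata", "synthetic_region.vcf", package = "towge")
  ph <- system.file("extdata", "synthetic_pheno.tsv", package = "towge")
  res <- suppressWarnings(run_region_test(list(
    genotypes = vcf, pheno = ph, trait = "bmi", covariates = "age",
    env = "packyears", sample_col = "id", methods = "tow",
    B = 100L, seed = 1L, min_maf = 0
  )))
  expect_equal(nrow(res), 1L)
  expect_equal(res$n, 60L)
  expect_true(res$p_value >= 1 / 101)
})

test_that("step-up escalation re-runs promising regions at 10x permutations", {
  set.seed(93)
  n <- 150
  g <- simulate_genotypes(n, c(0.03, 0.2), seed = 93)
  e <- rnorm(n)
  # plant a strong interaction so the first-pass p is < 0.1
  y <- 0.8 * g$dosages[, 1] * e + rnorm(n)
  df <- data.frame(y = y, e = e)
  res <- ge_region_test(df, g, trait = "y", env = "e", methods = "tow",
                        B = 100L, seed = 3, min_maf = 0, step_up = TRUE)
  expect_equal(res$n_perm, 1000)
  expect_match(res$note, "step-up")
})
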