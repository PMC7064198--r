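# Synthetic data generation for the simulation study: a 10-variant region
# panel (8 rare, 2 common by default) with independent binomial dosages, and
# a quantitative trait from a linear model with covariate, environment,
# genotype main-effect, and GE interaction terms.

#' Define a simulation scenario
#'
#' A scenario fixes everything one cell of the simulation study needs: the
#' sample size, the MAF panel, which effects are present and how large they
#' are, and the Monte-Carlo sizes. Defaults mirror the study design used for
#' type-I-error calibration: `n = 2000` unrelated individuals, a continuous
#' trait
#' \deqn{y = 0.5 x_1 + 0.5 x_2 + \alpha_1 E + G' \alpha_2 + S' \beta +
#'   S_c \beta_c + \epsilon, \quad \epsilon \sim N(0, 1),}
#' with `x_1, E ~ N(0,1)`, `x_2 ~ Bernoulli(0.5)`, environment coefficient
#' `alpha1 = 0.015`, and (when `include_main`) rare-variant main effects of
#' magnitude `alpha2_mag = 0.3` with random signs. Under the null all
#' interaction coefficients are zero; under an alternative, `causal_count`
#' rare variants get interaction coefficients of magnitude `c` (a fraction
#' `pct_positive` of them positive, the causal set drawn once per scenario),
#' and `common_causal` adds one common-variant interaction with coefficient
#' `+2c`.
#'
#' When `maf_panel` is `NULL` a 10-variant panel is drawn once from the
#' scenario seed: 8 rare MAFs from Uniform(0.001, 0.05) and 2 common from
#' Uniform(0.05, 0.5).
#'
#' @param n sample size.
#' @param maf_panel per-variant MAFs, or `NULL` for the default panel.
#' @param n_rare,n_common panel composition used when `maf_panel` is `NULL`.
#' @param include_main include genotype main effects (`alpha2_mag`, random
#'   signs) on the rare variants.
#' @param alpha1 environment main-effect coefficient.
#' @param alpha2_mag magnitude of each rare-variant main effect.
#' @param causal_count number of rare variants with nonzero interaction
#'   coefficients.
#' @param pct_positive fraction of causal interaction coefficients that are
#'   positive.
#' @param c magnitude of each nonzero rare interaction coefficient.
#' @param common_causal give one common variant an interaction coefficient
#'   `+2c`.
#' @param replicates Monte-Carlo replicates per experiment.
#' @param B permutations per test.
#' @param alpha_levels nominal significance levels reported.
#' @param seed scenario seed; drives the panel, the causal set, and every
#'   replicate stream.
#' @returns an object of class `ge_scenario`.
#' @export
ge_scenario <- function(n = 2000, maf_panel = NULL, n_rare = 8, n_common = 2,
                        include_main = TRUE, alpha1 = 0.015, alpha2_mag = 0.3,
                        causal_count = 0, pct_positive = 1, c = 0,
                        common_causal = FALSE, replicates = 500, B = 500,
                        alpha_levels = c(0.05, 0.01, 0.001), seed = 1L) {
  if (is.null(maf_panel)) {
    set.seed(seed)
    maf_panel <- c(stats::runif(n_rare, 0.001, 0.05),
                   stats::runif(n_common, 0.05, 0.5))
    names(maf_panel) <- paste0("v", seq_along(maf_panel))
  }
  stopifnot(all(maf_panel > 0), all(maf_panel <= 0.5),
            pct_positive >= 0, pct_positive <= 1, c >= 0)
  rare_panel <- which(maf_panel < 0.05)
  if (causal_count > length(rare_panel)) {
    stop("causal_count exceeds the number of rare variants in the panel.")
  }
  # causal set fixed per scenario: drawn once, uniformly among rare variants
  causal_idx <- integer(0)
  if (causal_count > 0) {
    set.seed(seed + 1L)
    causal_idx <- sort(sample(rare_panel, causal_count))
  }
  common_causal_idx <- if (common_causal) {
    commons <- setdiff(seq_along(maf_panel), rare_panel)
    if (!length(commons)) stop("common_causal requires a common variant in the panel.")
    commons[1L]
  } else integer(0)

  structure(
    list(n = n, maf_panel = maf_panel, include_main = include_main,
         alpha1 = alpha1, alpha2_mag = alpha2_mag,
         causal_count = causal_count, causal_idx = causal_idx,
         pct_positive = pct_positive, c = c,
         common_causal = common_causal, common_causal_idx = common_causal_idx,
         replicates = replicates, B = B, alpha_levels = alpha_levels,
         seed = as.integer(seed)),
    class = "ge_scenario"
  )
}

#' @export
print.ge_scenario <- function(x, ...) {
  cat(sprintf("<ge_scenario> n = %d, %d variants (%d rare), %s main effects\n",
              x$n, length(x$maf_panel), sum(x$maf_panel < 0.05),
              if (x$include_main) "with" else "no"))
  if (x$causal_count > 0 || x$common_causal) {
    cat(sprintf("  alternative: %d causal rare (|beta| = %g, %.0f%% positive)%s\n",
                x$causal_count, x$c, 100 * x$pct_positive,
                if (x$common_causal) sprintf(", common beta = %g", 2 * x$c) else ""))
  } else {
    cat("  null: all interaction effects zero\n")
  }
  cat(sprintf("  %d replicates x %d permutations, seed %d\n",
              x$replicates, x$B, x$seed))
  invisible(x)
}

#' Simulate region genotypes
#'
#' Dosages are independent Binomial(2, MAF) draws across individuals and
#' variants -- rare-variant sites in a short region carry essentially
#' independent minor alleles, which is the regime the optimal-weight
#' derivation assumes.
#'
#' @param n individuals.
#' @param maf_panel per-variant minor allele frequencies.
#' @param seed RNG seed.
#' @returns a [ge_genotypes] object (MAFs re-estimated from the sample).
#' @export
simulate_genotypes <- function(n, maf_panel, seed = 1L) {
  stopifnot(n >= 1, all(maf_panel >= 0), all(maf_panel <= 0.5))
  set.seed(seed)
  dos <- vapply(maf_panel, function(q) stats::rbinom(n, 2L, q), numeric(n))
  if (n == 1L) dos <- matrix(dos, nrow = 1L)
  ids <- names(maf_panel)
  if (is.null(ids)) ids <- paste0("v", seq_along(maf_panel))
  colnames(dos) <- ids
  ge_genotypes(dos)
}

#' Simulate a trait from a scenario
#'
#' Draws covariates (`x1` standard normal, `x2` Bernoulli(0.5)), a standard
#' normal environment `e`, unit-variance normal noise, and assembles the
#' trait from the scenario's linear model: covariate effects 0.5, environment
#' effect `alpha1`, rare-variant main effects of magnitude `alpha2_mag` with
#' signs drawn fresh per replicate (when `include_main`), interaction effects
#' `beta` on the scenario's causal set, and `+2c` on one common variant when
#' `common_causal`.
#'
#' @param g a [ge_genotypes] object with as many variants as the scenario
#'   panel.
#' @param scen a [ge_scenario].
#' @param seed RNG seed for this replicate.
#' @returns a [ge_pheno] object (trait `y`, covariates `x1`, `x2`,
#'   environment `e`); the generating coefficients are attached as
#'   `$sim_truth`.
#' @export
simulate_trait <- function(g, scen, seed = 1L) {
  stopifnot(inherits(g, "ge_genotypes"), inherits(scen, "ge_scenario"))
  m <- length(scen$maf_panel)
  if (ncol(g$dosages) != m) stop("genotypes do not match the scenario panel.")
  n <- nrow(g$dosages)

  set.seed(seed)
  x1 <- stats::rnorm(n)
  x2 <- stats::rbinom(n, 1L, 0.5)
  e <- stats::rnorm(n)
  eps <- stats::rnorm(n)

  alpha2 <- numeric(m)
  if (scen$include_main) {
    rare_panel <- which(scen$maf_panel < 0.05)
    alpha2[rare_panel] <- scen$alpha2_mag * sample(c(-1, 1), length(rare_panel),
                                                   replace = TRUE)
  }
  beta <- numeric(m)
  if (scen$causal_count > 0) {
    k <- scen$causal_count
    n_pos <- round(scen$pct_positive * k)
    signs <- c(rep(1, n_pos), rep(-1, k - n_pos))
    beta[scen$causal_idx] <- scen$c * signs
  }
  if (scen$common_causal) beta[scen$common_causal_idx] <- 2 * scen$c

  G <- g$dosages
  S <- G * e
  y <- 0.5 * x1 + 0.5 * x2 + scen$alpha1 * e +
    as.numeric(G %*% alpha2) + as.numeric(S %*% beta) + eps

  ph <- ge_pheno(data.frame(y = y, x1 = x1, x2 = x2, e = e),
                 trait = "y", covariates = c("x1", "x2"), env = "e",
                 trait_type = "quantitative")
  ph$sim_truth <- list(alpha2 = alpha2, beta = beta)
  ph
}
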