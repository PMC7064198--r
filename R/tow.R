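#' Score statistic for a fixed weight vector
#'
#' The region score statistic for association between the residualized trait
#' and a weighted combination `s~_i = sum_j w_j s~_ij` of residualized GE
#' interaction columns:
#' \deqn{S(w) = \frac{n \left(\sum_i (\tilde y_i - \bar{\tilde y})
#'   (\tilde s_i - \bar{\tilde s})\right)^2}
#'   {\sum_i (\tilde y_i - \bar{\tilde y})^2 \sum_i (\tilde s_i - \bar{\tilde s})^2}}
#' with the exact denominator (all cross terms of the combination's variance
#' included). `S` is invariant to rescaling `w` by a nonzero constant.
#'
#' @param r a [residualize()] result.
#' @param w numeric weights, one per retained interaction column.
#' @returns the scalar statistic.
#' @export
score_statistic <- function(r, w) {
  stopifnot(inherits(r, "ge_residuals"))
  p <- ncol(r$S_res)
  if (length(w) != p) stop("need one weight per retained column (", p, ").")
  if (all(w == 0)) stop("at least one weight must be nonzero.")
  comb <- as.numeric(r$S_res %*% w)
  sc <- comb - mean(comb)
  if (sum(sc^2) < .Machine$double.eps) stop("degenerate weight vector")
  yc <- r$y_res - mean(r$y_res)
  r$n * sum(yc * sc)^2 / (sum(yc^2) * sum(sc^2))
}

#' Analytically optimal per-column weights
#'
#' Under the approximation that rare-variant interaction columns are
#' uncorrelated (so the combination variance is diagonal), the score
#' statistic is maximized by `w_j = U_j / V_j`, where
#' `U_j = sum_i (y~_i - mean(y~)) (s~_ij - mean(s~_j))` is the per-column
#' score and `V_j = sum_i (s~_ij - mean(s~_j))^2` its permutation-fixed
#' denominator. The weight is signed by the trait-interaction correlation
#' (direction-adaptive) and inversely proportional to the column's variation
#' (up-weighting rare-variant interactions).
#'
#' @param r a [residualize()] result.
#' @returns an object of class `ge_weights`: list with `w`, `U`, `V`
#'   (each length p, named by column).
#' @export
optimal_weights <- function(r) {
  stopifnot(inherits(r, "ge_residuals"))
  if (ncol(r$S_res) < 1L) stop("no retained interaction columns.")
  Sc <- scale(r$S_res, center = TRUE, scale = FALSE)
  yc <- r$y_res - mean(r$y_res)
  U <- as.numeric(crossprod(Sc, yc))
  V <- colSums(Sc^2)
  if (any(V <= 0)) stop("zero-variance interaction column; residualize first.")
  structure(
    list(w = stats::setNames(U / V, colnames(r$S_res)), U = U, V = V),
    class = "ge_weights"
  )
}

#' @export
print.ge_weights <- function(x, ...) {
  cat("<ge_weights>\n")
  print(round(x$w, 6))
  invisible(x)
}

#' @method tidy ge_weights
#' @export
tidy.ge_weights <- function(x, ...) {
  tibble::tibble(
    column = if (is.null(names(x$w))) paste0("s", seq_along(x$w)) else names(x$w),
    weight = unname(x$w), score = x$U, score_ss = x$V
  )
}

#' The TOW-GE test statistic
#'
#' The score test of the optimally weighted combination of GE interactions:
#' \deqn{T = \sum_i (\tilde y_i - \bar{\tilde y})(\tilde s^0_i - \bar{\tilde s}^0),
#'   \qquad \tilde s^0_i = \sum_j w^0_j \tilde s_{ij},}
#' which collapses algebraically to `T = sum_j U_j^2 / V_j >= 0`. The factor
#' `sum_i (y~_i - mean(y~))^2` of the full score statistic is constant under
#' trait permutation and is omitted.
#'
#' @param r a [residualize()] result.
#' @returns the scalar statistic (nonnegative).
#' @export
tow_ge_statistic <- function(r) {
  ow <- optimal_weights(r)
  sum(ow$U^2 / ow$V)
}

# ---- shared permutation engine ----------------------------------------
#
# All implemented statistics are functions of the per-column cross-products
# U^(b) = Sc' yc[perm_b] between the fixed centered interaction columns and
# the permuted centered trait residuals (column variances V and, for CMC,
# the column covariance are permutation-invariant). The engine therefore
# computes the p x (B+1) matrix of cross-products once (b = 0 observed) and
# each statistic maps its columns to values.

perm_crossprods <- function(y_res, S_res, B, seed, chunk = 2000L) {
  n <- length(y_res)
  yc <- y_res - mean(y_res)
  Sc <- scale(S_res, center = TRUE, scale = FALSE)
  U <- matrix(NA_real_, nrow = ncol(Sc), ncol = B + 1L)
  U[, 1L] <- crossprod(Sc, yc)
  set.seed(seed)
  done <- 0L
  while (done < B) {
    nb <- min(chunk, B - done)
    Ym <- vapply(seq_len(nb), function(b) yc[sample.int(n)], numeric(n))
    U[, done + 1L + seq_len(nb)] <- crossprod(Sc, Ym)
    done <- done + nb
  }
  U
}

pvalue_from_ensemble <- function(stats, convention) {
  # stats[1] observed, stats[-1] permuted
  t0 <- stats[1L]
  B <- length(stats) - 1L
  if (stats::sd(stats) < .Machine$double.eps * max(1, abs(t0))) {
    warning("statistic is constant under permutation; p-value set to 1.")
    return(1)
  }
  if (convention == "add_one") {
    (1 + sum(stats[-1L] >= t0)) / (B + 1)
  } else {
    sum(stats[-1L] > t0) / B
  }
}

new_ge_test <- function(method, statistic, p_value, n_perm, seed, convention,
                        weights = NULL, perm_stats = NULL, notes = list()) {
  structure(
    list(method = method, statistic = statistic, p_value = p_value,
         n_perm = n_perm, seed = seed, convention = convention,
         weights = weights, perm_stats = perm_stats, notes = notes),
    class = "ge_test"
  )
}

#' Permutation p-value for a region interaction statistic
#'
#' Permutes the residualized trait (interaction columns fixed), recomputes
#' the statistic for each shuffle -- data-dependent ingredients such as the
#' optimal weights are re-estimated inside every permutation -- and returns
#' the rank-based p-value. The default add-one convention
#' `p = (1 + #\{T^{(b)} >= T^{(0)}\}) / (B + 1)` is a valid test with
#' `p >= 1/(B+1)`; `convention = "raw"` gives the plain
#' `#\{T^{(b)} > T^{(0)}\} / B` count, which can return 0.
#'
#' @param r a [residualize()] result.
#' @param statistic `"tow"` (default), or a function mapping a cross-product
#'   vector `U` (one entry per retained column) to a scalar statistic given
#'   the permutation-fixed column sums of squares `V`.
#' @param B number of permutations (>= 1).
#' @param seed RNG seed; all randomness flows from it.
#' @param convention `"add_one"` or `"raw"`.
#' @param keep_perms retain the permuted statistic ensemble in the result
#'   (for diagnostics / [autoplot.ge_test()]).
#' @returns a `ge_test` object: statistic, p-value, permutation count, seed,
#'   optimal weights (for `"tow"`), and notes.
#' @examples
#' g <- simulate_genotypes(80, maf_panel = c(0.03, 0.04, 0.2), seed = 2)
#' ph <- ge_pheno(data.frame(y = rnorm(80), e = rnorm(80)),
#'                trait = "y", env = "e")
#' r <- residualize(ph, g)
#' permutation_pvalue(r, B = 199, seed = 7)
#' @export
permutation_pvalue <- function(r, statistic = "tow", B = 1000L, seed = 1L,
                               convention = c("add_one", "raw"),
                               keep_perms = TRUE) {
  convention <- match.arg(convention)
  stopifnot(inherits(r, "ge_residuals"), B >= 1)
  if (ncol(r$S_res) < 1L) stop("no retained interaction columns.")
  Sc <- scale(r$S_res, center = TRUE, scale = FALSE)
  V <- colSums(Sc^2)
  Umat <- perm_crossprods(r$y_res, r$S_res, B = B, seed = seed)

  if (identical(statistic, "tow")) {
    stat_fun <- function(U, V) sum(U^2 / V)
    method <- "TOW-GE"
  } else if (is.function(statistic)) {
    stat_fun <- statistic
    method <- "custom"
  } else {
    stop("`statistic` must be \"tow\" or a function(U, V).")
  }
  stats <- apply(Umat, 2, stat_fun, V = V)
  p <- pvalue_from_ensemble(stats, convention)

  new_ge_test(
    method = method, statistic = stats[1L], p_value = p, n_perm = B,
    seed = seed, convention = convention,
    weights = if (identical(statistic, "tow")) optimal_weights(r) else NULL,
    perm_stats = if (keep_perms) stats[-1L] else NULL,
    notes = list(dropped_idx = r$dropped_idx)
  )
}

#' TOW-GE permutation test
#'
#' Convenience wrapper: [permutation_pvalue()] with the TOW-GE statistic.
#'
#' @inheritParams permutation_pvalue
#' @returns a `ge_test` object.
#' @export
tow_ge_test <- function(r, B = 1000L, seed = 1L,
                        convention = c("add_one", "raw"), keep_perms = TRUE) {
  permutation_pvalue(r, statistic = "tow", B = B, seed = seed,
                     convention = match.arg(convention), keep_perms = keep_perms)
}

#' @export
print.ge_test <- function(x, ...) {
  cat(sprintf("<ge_test> %s: T = %.6g, p = %.4g (%d permutations, %s convention)\n",
              x$method, x$statistic, x$p_value, x$n_perm, x$convention))
  if (!is.null(x$notes$lambda_star)) {
    cat(sprintf("  lambda* = %.3g (descriptive only)\n", x$notes$lambda_star))
  }
  invisible(x)
}

#' @method tidy ge_test
#' @export
tidy.ge_test <- function(x, ...) {
  tibble::tibble(
    method = x$method, statistic = x$statistic, p_value = x$p_value,
    n_perm = x$n_perm, seed = x$seed, convention = x$convention
  )
}

#' @method glance ge_test
#' @export
glance.ge_test <- function(x, ...) {
  tibble::tibble(
    method = x$method, statistic = x$statistic, p_value = x$p_value,
    n_perm = x$n_perm,
    p_floor = 1 / (x$n_perm + 1),
    n_dropped = length(x$notes$dropped_idx),
    lambda_star = if (is.null(x$notes$lambda_star)) NA_real_ else x$notes$lambda_star
  )
}

#' Permutation-ensemble diagnostic plot
#'
#' Histogram of the permuted statistic ensemble with the observed value
#' marked; requires the test to have been run with `keep_perms = TRUE`.
#'
#' @param object a `ge_test` object.
#' @param ... unused.
#' @returns a ggplot object.
#' @method autoplot ge_test
#' @export
autoplot.ge_test <- function(object, ...) {
  if (is.null(object$perm_stats)) {
    stop("test was run with keep_perms = FALSE; no ensemble to plot.")
  }
  df <- tibble::tibble(statistic = object$perm_stats)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$statistic,
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(
      title = sprintf("%s permutation ensemble (B = %d)", object$method, object$n_perm),
      subtitle = sprintf("observed T = %.4g, p = %.4g", object$statistic, object$p_value),
      x = "permuted statistic", y = "count"
    ) +
    ggplot2::theme_minimal()
}
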