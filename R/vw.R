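#' Split a residual set into rare- and common-variant sides
#'
#' Partitions the retained residualized interaction columns by the
#' rare/common status of their underlying variants. Both sides share the
#' same residualized trait; columns dropped during residualization stay
#' dropped on their side.
#'
#' @param r a [residualize()] result whose column indices refer to the
#'   variants in `part`.
#' @param part a [classify_variants()] partition.
#' @returns list with elements `rare` and `common`, each a `ge_residuals`.
#' @export
split_by_partition <- function(r, part) {
  stopifnot(inherits(r, "ge_residuals"), inherits(part, "ge_partition"))
  all_idx <- sort(c(r$kept_idx, r$dropped_idx))
  if (!all(part$rare_idx %in% all_idx) || !all(part$common_idx %in% all_idx)) {
    stop("partition indices do not match the residual set's columns.")
  }
  take <- function(side_idx) {
    keep_cols <- which(r$kept_idx %in% side_idx)
    new_ge_residuals(
      y_res = r$y_res,
      S_res = r$S_res[, keep_cols, drop = FALSE],
      kept_idx = r$kept_idx[keep_cols],
      dropped_idx = intersect(r$dropped_idx, side_idx),
      design_rank = r$design_rank
    )
  }
  rare <- take(part$rare_idx)
  common <- take(part$common_idx)
  if (ncol(rare$S_res) == 0L || ncol(common$S_res) == 0L) {
    stop("one side of the rare/common split is empty; use tow_ge_test() on the full set instead.")
  }
  list(rare = rare, common = common)
}

#' Variance-standardized mixture of rare- and common-side statistics
#'
#' \deqn{T_\lambda = \lambda \frac{T_r}{\mathrm{var}(T_r)} +
#'   (1 - \lambda) \frac{T_c}{\mathrm{var}(T_c)}}
#' The denominators are variances (not standard deviations) of the two
#' TOW-GE statistics, estimated from their permutation ensembles.
#'
#' @param T_r,T_c rare- and common-side statistic values (scalar or vector).
#' @param var_r,var_c positive ensemble variances.
#' @param lam mixing weight in `[0, 1]`; `lam = 1` is rare-only.
#' @returns numeric of the same length as `T_r`.
#' @export
t_lambda <- function(T_r, T_c, var_r, var_c, lam) {
  stopifnot(var_r > 0, var_c > 0, lam >= 0, lam <= 1)
  lam * T_r / var_r + (1 - lam) * T_c / var_c
}

#' VW-TOW-GE: variable-weight combination of rare- and common-variant
#' interaction tests
#'
#' Applies TOW-GE separately to the rare- and common-variant interaction
#' columns and combines the two statistics as [t_lambda()] over the grid
#' `lambda_k = k/K, k = 0..K`. The final statistic is
#' `min_k p_{lambda_k}`, calibrated by a nested permutation transformation:
#' one shared permutation stream drives both sides (for each shuffle `b` the
#' same permuted trait yields `T_r^(b)` and `T_c^(b)`, preserving their
#' dependence); ensemble variances use all `b = 0..B`; each `T_{lambda_k}^(b)`
#' is rank-transformed to
#' `p_{lambda_k}^(b) = #\{d : T_{lambda_k}^(d) > T_{lambda_k}^(b)\} / B`,
#' minimized over `k` to give `p^(b)`, and the reported p-value compares
#' `p^(0)` with the permuted minima (add-one convention
#' `(1 + #\{b >= 1 : p^(b) <= p^(0)\}) / (B + 1)` by default; `"raw"` uses
#' the strict-`<` count over `b = 0..B` divided by `B`).
#'
#' @param r a [residualize()] result covering both rare and common columns.
#' @param part a [classify_variants()] partition.
#' @param B number of permutations.
#' @param K number of grid subintervals (grid has `K + 1` points).
#' @param seed RNG seed.
#' @param convention `"add_one"` or `"raw"`.
#' @param keep_perms retain the per-permutation min-p ensemble.
#' @returns a `ge_test` object; `notes$lambda_star` records the grid point
#'   minimizing the observed p (descriptive only), `notes$var_r` /
#'   `notes$var_c` the ensemble variances.
#' @export
vw_tow_ge_test <- function(r, part, B = 1000L, K = 10L, seed = 1L,
                           convention = c("add_one", "raw"),
                           keep_perms = TRUE) {
  convention <- match.arg(convention)
  stopifnot(B >= 1, K >= 1)
  sides <- split_by_partition(r, part)
  rare_cols <- which(r$kept_idx %in% sides$rare$kept_idx)
  common_cols <- which(r$kept_idx %in% sides$common$kept_idx)

  Sc <- scale(r$S_res, center = TRUE, scale = FALSE)
  V <- colSums(Sc^2)
  Umat <- perm_crossprods(r$y_res, r$S_res, B = B, seed = seed)
  T_r <- colSums(Umat[rare_cols, , drop = FALSE]^2 / V[rare_cols])
  T_c <- colSums(Umat[common_cols, , drop = FALSE]^2 / V[common_cols])

  var_r <- stats::var(T_r)
  var_c <- stats::var(T_c)
  if (!(var_r > 0) || !(var_c > 0)) {
    stop("degenerate side: a statistic ensemble has zero variance.")
  }

  lambdas <- seq(0, 1, length.out = K + 1L)
  # p_lambda[k, b]: share of the ensemble strictly exceeding T_lambda^(b)
  p_lambda <- matrix(NA_real_, nrow = K + 1L, ncol = B + 1L)
  for (k in seq_along(lambdas)) {
    Tk <- t_lambda(T_r, T_c, var_r, var_c, lambdas[k])
    p_lambda[k, ] <- (length(Tk) - rank(Tk, ties.method = "max")) / B
  }
  p_min <- apply(p_lambda, 2, min)
  lambda_star <- lambdas[which.min(p_lambda[, 1L])]

  p <- if (convention == "add_one") {
    (1 + sum(p_min[-1L] <= p_min[1L])) / (B + 1)
  } else {
    sum(p_min < p_min[1L]) / B
  }

  new_ge_test(
    method = "VW-TOW-GE", statistic = p_min[1L], p_value = p, n_perm = B,
    seed = seed, convention = convention,
    perm_stats = if (keep_perms) p_min[-1L] else NULL,
    notes = list(
      lambda_star = lambda_star, K = K,
      var_r = var_r, var_c = var_c,
      T_r = T_r[1L], T_c = T_c[1L],
      dropped_idx = r$dropped_idx
    )
  )
}
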