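# Modified burden comparators: the classical WSS and CMC aggregation schemes
# re-expressed as permutation score tests on the residualized trait and
# residualized GE interaction columns. The aggregation rules are the
# classical ones; the test statistics are reconstructions (the originals use
# a rank-sum test and a Hotelling T^2, which do not apply to residualized
# interaction data).

#' Modified weighted-sum (WSS) test for GE interactions
#'
#' Collapses the residualized interaction columns into a single burden
#' column with Madsen-Browning weights,
#' `s^W_i = sum_j s~_ij / sqrt(n q_j (1 - q_j))`, where `q_j` is the sample
#' MAF of variant `j` on the whole sample, then tests the squared (signed)
#' score `(sum_i (y~_i - mean(y~)) (s^W_i - mean(s^W)))^2` by permutation.
#' Because aggregation happens before squaring, the statistic is
#' direction-sensitive: interaction effects of opposite sign cancel.
#'
#' @param r a [residualize()] result.
#' @param g the [ge_genotypes] object the residual set was built from
#'   (supplies the sample MAFs for the weights).
#' @inheritParams permutation_pvalue
#' @returns a `ge_test` object.
#' @export
wss_ge_test <- function(r, g, B = 1000L, seed = 1L,
                        convention = c("add_one", "raw"), keep_perms = TRUE) {
  convention <- match.arg(convention)
  stopifnot(inherits(r, "ge_residuals"), inherits(g, "ge_genotypes"))
  q <- g$maf[r$kept_idx]
  if (length(q) != ncol(r$S_res)) stop("genotype object does not match the residual set.")
  if (any(q <= 0)) stop("monomorphic variant among retained columns; cannot weight.")
  a <- 1 / sqrt(r$n * q * (1 - q))

  out <- permutation_pvalue(
    r, statistic = function(U, V) sum(a * U)^2,
    B = B, seed = seed, convention = convention, keep_perms = keep_perms
  )
  out$method <- "WSS-GE"
  out$notes$mb_weights <- a
  out
}

#' Modified CMC (collapsing) test for GE interactions
#'
#' Builds the classical combined-multivariate-and-collapsing design on the
#' interaction scale: one collapsed rare column, `E_i` times the indicator
#' that individual `i` carries a minor allele at any rare variant,
#' residualized against the same adjustment design as the other interaction
#' columns, plus each common-variant residualized interaction column kept
#' as-is. The statistic is the multivariate score form
#' `U' V^{-1} U` with `U` the per-column trait-column inner products and
#' `V = (sum_i y~_i^2 / n) * C'C` for the centered column matrix `C`; both
#' `V` and the column matrix are fixed under trait permutation, so the exact
#' normalization affects power but not validity. A singular `V` falls back
#' to the Moore-Penrose pseudo-inverse with a warning.
#'
#' @param r a [residualize()] result (must come from [residualize()], which
#'   stores the adjustment design).
#' @param part a [classify_variants()] partition.
#' @param g the [ge_genotypes] object (raw dosages define rare carriers).
#' @param E environment vector (as used to build the interactions).
#' @inheritParams permutation_pvalue
#' @returns a `ge_test` object; `notes$design_cols` describes the collapsed
#'   design columns.
#' @export
cmc_ge_test <- function(r, part, g, E, B = 1000L, seed = 1L,
                        convention = c("add_one", "raw"), keep_perms = TRUE) {
  convention <- match.arg(convention)
  stopifnot(inherits(r, "ge_residuals"), inherits(part, "ge_partition"),
            inherits(g, "ge_genotypes"))
  if (length(E) != r$n) stop("environment vector length does not match n.")

  cols <- list(); desc <- character(0)
  rare_idx <- intersect(part$rare_idx, seq_along(g$maf))
  if (length(rare_idx)) {
    carrier <- as.numeric(rowSums(g$dosages[, rare_idx, drop = FALSE] > 0) > 0)
    collapse_raw <- E * carrier
    collapse <- if (!is.null(r$design_qr)) qr.resid(r$design_qr, collapse_raw) else
      collapse_raw - mean(collapse_raw)
    if (stats::var(collapse) > 1e-12 * max(1, stats::var(collapse_raw), na.rm = TRUE)) {
      cols <- c(cols, list(collapse)); desc <- c(desc, "rare_collapse")
    } else {
      warning("collapsed rare column is degenerate (no informative carriers); dropped.")
    }
  }
  common_cols <- which(r$kept_idx %in% part$common_idx)
  for (j in common_cols) {
    cols <- c(cols, list(r$S_res[, j]))
    desc <- c(desc, colnames(r$S_res)[j] %||% paste0("common_", j))
  }
  if (!length(cols)) stop("no usable columns for the CMC design.")
  C <- do.call(cbind, cols)
  if (r$n <= ncol(C)) stop("need more individuals than CMC design columns.")

  yc <- r$y_res - mean(r$y_res)
  Cc <- scale(C, center = TRUE, scale = FALSE)
  Vmat <- (sum(yc^2) / r$n) * crossprod(Cc)
  Vinv <- tryCatch(solve(Vmat), error = function(e) {
    warning("singular CMC covariance; using pseudo-inverse.")
    MASS::ginv(Vmat)
  })

  Umat <- perm_crossprods(r$y_res, C, B = B, seed = seed)
  stats <- colSums((Vinv %*% Umat) * Umat)
  p <- pvalue_from_ensemble(stats, convention)

  new_ge_test(
    method = "CMC-GE", statistic = stats[1L], p_value = p, n_perm = B,
    seed = seed, convention = convention,
    perm_stats = if (keep_perms) stats[-1L] else NULL,
    notes = list(design_cols = desc, dropped_idx = r$dropped_idx)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
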