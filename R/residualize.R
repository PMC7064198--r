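#' Residualize the trait and interaction columns on covariates, environment,
#' and genotype main effects
#'
#' The score tests in this package isolate interaction effects by first
#' projecting both the trait and every GE interaction column onto the
#' orthogonal complement of the adjustment design
#' `X~ = [1, X, E, G]` (intercept, covariates, environmental main effect,
#' and the main-effect dosages of all region variants). Testing the
#' interaction coefficients in the full generalized linear model is then
#' equivalent to testing association between the residualized trait `y~` and
#' the residualized interaction columns `S~`.
#'
#' Residuals are computed by least squares via a pivoted QR decomposition.
#' When the design is rank deficient (frequent with many rare variants whose
#' dosage columns are nearly collinear) the residuals are still well defined
#' -- they are the projection onto the complement of the design's column
#' space, identical for every least-squares solution -- so no columns are
#' pruned. Interaction columns whose residual variance collapses (e.g. an
#' interaction that is itself a linear combination of design columns) are
#' moved to `dropped_idx` with a warning.
#'
#' For a binary trait the default is still an ordinary linear-model
#' residualization; validity of the downstream tests rests on the permutation
#' null rather than on the linear model. `binary_link = "logistic"` instead
#' uses Pearson residuals from a logistic fit of the trait on the design
#' (interaction columns are always residualized linearly).
#'
#' @param pheno a [ge_pheno] object.
#' @param g a [ge_genotypes] object (its dosages form the main-effect block);
#'   pass `NULL` to omit genotype main effects from the adjustment.
#' @param S interaction matrix from [build_interactions()]; defaults to
#'   `build_interactions(g, pheno$E)`.
#' @param binary_link `"linear"` (default) or `"logistic"`, used only when
#'   `pheno$trait_type == "binary"`.
#' @param var_tol relative residual-variance tolerance below which an
#'   interaction column is declared degenerate and dropped.
#' @returns an object of class `ge_residuals`: list with `y_res` (length-n
#'   residualized trait), `S_res` (n x p matrix of retained residualized
#'   interaction columns), `kept_idx` / `dropped_idx` (column indices into
#'   the original `S`), `design_rank`, and `n`.
#' @examples
#' g <- simulate_genotypes(100, maf_panel = c(0.04, 0.2), seed = 1)
#' ph <- ge_pheno(
#'   data.frame(y = rnorm(100), x = rnorm(100), e = rnorm(100)),
#'   trait = "y", covariates = "x", env = "e"
#' )
#' r <- residualize(ph, g)
#' crossprod(r$S_res, r$y_res)  # per-column scores
#' @export
residualize <- function(pheno, g = NULL, S = NULL,
                        binary_link = c("linear", "logistic"),
                        var_tol = 1e-12) {
  binary_link <- match.arg(binary_link)
  stopifnot(inherits(pheno, "ge_pheno"))
  n <- length(pheno$y)
  G <- if (is.null(g)) NULL else {
    stopifnot(inherits(g, "ge_genotypes"))
    if (nrow(g$dosages) != n) stop("genotype rows do not match phenotype rows.")
    g$dosages
  }
  if (is.null(S)) {
    if (is.null(g)) stop("supply `S` when `g` is NULL.")
    S <- build_interactions(g, pheno$E)
  }
  S <- as.matrix(S)
  if (nrow(S) != n) stop("interaction matrix rows do not match phenotype rows.")

  design <- cbind(`(Intercept)` = 1, pheno$X, E = pheno$E, G)
  qr_d <- qr(design)
  if (n <= qr_d$rank) stop("need more individuals than the design rank.")

  resid_on <- function(v) qr.resid(qr_d, v)

  y_res <- if (pheno$trait_type == "binary" && binary_link == "logistic") {
    fit <- suppressWarnings(
      stats::glm.fit(design, pheno$y, family = stats::binomial())
    )
    mu <- fit$fitted.values
    (pheno$y - mu) / sqrt(pmax(mu * (1 - mu), .Machine$double.eps))
  } else {
    resid_on(pheno$y)
  }
  if (stats::var(y_res) < .Machine$double.eps) stop("trait residual is constant.")

  S_res <- apply(S, 2, resid_on)
  raw_var <- apply(S, 2, stats::var)
  res_var <- apply(S_res, 2, stats::var)
  degen <- res_var < var_tol * pmax(1, raw_var)
  if (any(degen)) {
    warning(sum(degen), " interaction column(s) degenerate after adjustment; dropped: ",
            paste(colnames(S)[degen], collapse = ", "))
  }

  structure(
    list(y_res = as.numeric(y_res),
         S_res = S_res[, !degen, drop = FALSE],
         kept_idx = unname(which(!degen)),
         dropped_idx = unname(which(degen)),
         design_rank = qr_d$rank,
         n = n,
         design_qr = qr_d),
    class = "ge_residuals"
  )
}

#' @export
print.ge_residuals <- function(x, ...) {
  cat(sprintf("<ge_residuals> n = %d, %d interaction column(s) retained, %d dropped, design rank %d\n",
              x$n, length(x$kept_idx), length(x$dropped_idx), x$design_rank))
  invisible(x)
}

# Internal: a bare residual set from components already residualized
# (used when splitting by partition and in tests).
new_ge_residuals <- function(y_res, S_res, kept_idx = seq_len(ncol(S_res)),
                             dropped_idx = integer(0), design_rank = NA_integer_) {
  structure(
    list(y_res = as.numeric(y_res), S_res = as.matrix(S_res),
         kept_idx = kept_idx, dropped_idx = dropped_idx,
         design_rank = design_rank, n = length(y_res),
         design_qr = NULL),
    class = "ge_residuals"
  )
}
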