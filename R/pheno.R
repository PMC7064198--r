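#' Assemble a phenotype/covariate table for region testing
#'
#' Takes a data frame of per-individual phenotypes and pulls out the trait,
#' the covariates, and the single environmental exposure used by the
#' interaction tests. Individuals with a missing value in any selected column
#' are listwise-deleted; the retained row indices are recorded so a genotype
#' matrix can be subset to match.
#'
#' @param data data frame, one row per individual.
#' @param trait name of the trait column (quantitative, or binary coded 0/1).
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @param env name of the environmental-factor column.
#' @param trait_type `"auto"` (binary iff the trait takes exactly the values
#'   0 and 1), `"quantitative"`, or `"binary"`.
#' @returns an object of class `ge_pheno`: list with `y` (numeric trait),
#'   `X` (n x q covariate matrix, q >= 0), `E` (environment vector),
#'   `trait_type`, and `kept_rows` (row indices of `data` retained).
#' @examples
#' ph <- ge_pheno(
#'   data.frame(bmi = rnorm(5), age = runif(5, 30, 60), smoke = rnorm(5)),
#'   trait = "bmi", covariates = "age", env = "smoke"
#' )
#' @export
ge_pheno <- function(data, trait, covariates = character(0), env,
                     trait_type = c("auto", "quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(data))
  need <- c(trait, covariates, env)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("column(s) not in `data`: ", paste(missing_cols, collapse = ", "))
  }
  sub <- data[need]
  keep <- stats::complete.cases(sub)
  if (!any(keep)) stop("no complete cases after listwise deletion.")
  sub <- sub[keep, , drop = FALSE]

  y <- as.numeric(sub[[trait]])
  E <- as.numeric(sub[[env]])
  if (stats::var(E) == 0) stop("environmental factor has zero variance.")
  X <- if (length(covariates)) {
    as.matrix(as.data.frame(lapply(sub[covariates], as.numeric)))
  } else {
    matrix(numeric(0), nrow = length(y), ncol = 0)
  }
  if (trait_type == "auto") {
    trait_type <- if (all(y %in% c(0, 1)) && length(unique(y)) == 2) "binary" else "quantitative"
  }
  if (trait_type == "binary" && !all(y %in% c(0, 1))) {
    stop("binary trait must be coded 0/1.")
  }
  if (stats::var(y) == 0) stop("trait is constant.")

  structure(
    list(y = y, X = X, E = E, trait_type = trait_type,
         kept_rows = which(keep)),
    class = "ge_pheno"
  )
}

#' @export
print.ge_pheno <- function(x, ...) {
  cat(sprintf("<ge_pheno> n = %d, %d covariate(s), %s trait\n",
              length(x$y), ncol(x$X), x$trait_type))
  invisible(x)
}
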