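#' Region-level GE interaction tests on a phenotype data frame
#'
#' The main user entry point: takes a per-individual phenotype data frame and
#' the region's genotypes, runs the full pipeline (cleaning, extreme-rare
#' filtering, interaction construction, residualization, permutation tests),
#' and returns one tidy row per method.
#'
#' @param data phenotype data frame, one row per individual.
#' @param genotypes a [ge_genotypes] object, a dosage matrix, or a file path
#'   accepted by [read_genotypes()].
#' @param trait,covariates,env column names in `data` (see [ge_pheno()]).
#' @param methods any of `"tow"`, `"vw"`, `"wss"`, `"cmc"`.
#' @param sample_col optional name of a sample-id column in `data`; when
#'   given and the genotype rows are named, individuals are matched by id
#'   (an empty intersection is an error).
#' @param maf_threshold rare/common MAF cutoff.
#' @param min_maf extreme-rare filter: variants with MAF below this are
#'   removed before testing (set 0 to disable).
#' @param B permutations; `K` VW grid subintervals; `seed` RNG seed;
#'   `convention` p-value convention (see [permutation_pvalue()]).
#' @param K VW-TOW-GE grid subintervals.
#' @param seed RNG seed; all randomness flows from it.
#' @param convention `"add_one"` or `"raw"`.
#' @param step_up when `TRUE`, any method with `p < 0.1` at the initial `B`
#'   is re-run at `10 * B` for a sharper p-value.
#' @returns a tibble with one row per method: `method`, `statistic`,
#'   `p_value`, `n_perm`, `seed`, `n`, `n_variants`, `n_rare`, `n_common`,
#'   `n_retained`, `n_dropped`, `lambda_star`, `note`.
#' @examples
#' g <- simulate_genotypes(150, maf_panel = c(0.02, 0.03, 0.2), seed = 5)
#' df <- data.frame(y = rnorm(150), age = rnorm(150), expo = rnorm(150))
#' ge_region_test(df, g, trait = "y", covariates = "age", env = "expo",
#'                methods = "tow", B = 99, seed = 3)
#' @export
ge_region_test <- function(data, genotypes, trait, covariates = character(0),
                           env, methods = c("tow", "vw"), sample_col = NULL,
                           maf_threshold = 0.05, min_maf = 0.001,
                           B = 10000L, K = 10L, seed = 1L,
                           convention = c("add_one", "raw"),
                           step_up = FALSE) {
  convention <- match.arg(convention)
  methods <- match.arg(methods, c("tow", "vw", "wss", "cmc"), several.ok = TRUE)

  g <- if (inherits(genotypes, "ge_genotypes")) genotypes
       else if (is.character(genotypes)) read_genotypes(genotypes)
       else ge_genotypes(genotypes)

  # sample matching
  if (!is.null(sample_col)) {
    if (is.null(rownames(g$dosages))) stop("genotypes carry no sample ids to match on.")
    shared <- intersect(as.character(data[[sample_col]]), rownames(g$dosages))
    if (!length(shared)) stop("no samples shared between phenotype and genotype inputs.")
    data <- data[match(shared, as.character(data[[sample_col]])), , drop = FALSE]
    g <- subset_individuals(g, match(shared, rownames(g$dosages)))
  } else if (nrow(data) != nrow(g$dosages)) {
    stop("phenotype rows (", nrow(data), ") do not match genotype rows (",
         nrow(g$dosages), "); supply `sample_col` to match by id.")
  }

  ph <- ge_pheno(data, trait = trait, covariates = covariates, env = env)
  if (length(ph$kept_rows) < nrow(g$dosages)) {
    g <- subset_individuals(g, ph$kept_rows)
  }

  if (min_maf > 0) {
    keep <- which(g$maf >= min_maf)
    if (!length(keep)) stop("no variants survive the extreme-rare filter (MAF >= ",
                            min_maf, ").")
    if (length(keep) < length(g$maf)) g <- subset_variants(g, keep)
  }

  part <- classify_variants(g, threshold = maf_threshold)
  r <- residualize(ph, g)

  run_method <- function(method, B_use) {
    note <- ""
    res <- switch(method,
      tow = tow_ge_test(r, B = B_use, seed = seed, convention = convention,
                        keep_perms = FALSE),
      vw = {
        if (!length(part$rare_idx) || !length(part$common_idx)) {
          note <- "one side empty; fell back to TOW-GE"
          warning("vw: ", note)
          tow_ge_test(r, B = B_use, seed = seed, convention = convention,
                      keep_perms = FALSE)
        } else {
          vw_tow_ge_test(r, part, B = B_use, K = K, seed = seed,
                         convention = convention, keep_perms = FALSE)
        }
      },
      wss = wss_ge_test(r, g, B = B_use, seed = seed, convention = convention,
                        keep_perms = FALSE),
      cmc = cmc_ge_test(r, part, g, ph$E, B = B_use, seed = seed,
                        convention = convention, keep_perms = FALSE)
    )
    list(res = res, note = note)
  }

  rows <- purrr::map(methods, function(method) {
    fit <- run_method(method, B)
    if (step_up && fit$res$p_value < 0.1) {
      fit <- run_method(method, 10L * B)
      fit$note <- paste0(fit$note, if (nzchar(fit$note)) "; ",
                         "step-up to B = ", 10L * B)
    }
    res <- fit$res
    tibble::tibble(
      method = res$method, statistic = res$statistic, p_value = res$p_value,
      n_perm = res$n_perm, seed = seed, n = r$n,
      n_variants = length(g$maf),
      n_rare = length(part$rare_idx), n_common = length(part$common_idx),
      n_retained = length(r$kept_idx), n_dropped = length(r$dropped_idx),
      lambda_star = res$notes$lambda_star %||% NA_real_,
      note = fit$note
    )
  })
  purrr::list_rbind(rows)
}

# Internal: row / column subsetting that keeps the ge_genotypes contract
# (MAFs recomputed on the subset so folding stays sample-based).
subset_individuals <- function(g, idx) ge_genotypes(g$dosages[idx, , drop = FALSE])
subset_variants <- function(g, idx) {
  ge_genotypes(g$dosages[, idx, drop = FALSE], variant_ids = g$variant_id[idx])
}

#' Run a region test from a configuration list
#'
#' File-level backend of the command-line interface: reads the genotype and
#' phenotype inputs named in `cfg`, runs [ge_region_test()], and (optionally)
#' writes the result table as TSV. All defaults mirror the command line:
#' `B = 10000`, extreme-rare filter at MAF < 0.001.
#'
#' @param cfg list with elements `genotypes` (path), `pheno` (path or data
#'   frame), `trait`, `covariates` (character vector), `env`, and optionally
#'   `sample_col`, `methods`, `maf_threshold`, `min_maf`, `B`, `K`, `seed`,
#'   `convention`, `step_up`, `out` (TSV path).
#' @returns the result tibble, invisibly when `cfg$out` is written.
#' @export
run_region_test <- function(cfg) {
  need <- c("genotypes", "pheno", "trait", "env")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config is missing: ", paste(miss, collapse = ", "))
  pheno <- if (is.data.frame(cfg$pheno)) cfg$pheno else {
    readr::read_tsv(cfg$pheno, show_col_types = FALSE, progress = FALSE)
  }
  res <- ge_region_test(
    data = pheno, genotypes = cfg$genotypes,
    trait = cfg$trait, covariates = cfg$covariates %||% character(0),
    env = cfg$env, methods = cfg$methods %||% c("tow", "vw"),
    sample_col = cfg$sample_col,
    maf_threshold = cfg$maf_threshold %||% 0.05,
    min_maf = cfg$min_maf %||% 0.001,
    B = cfg$B %||% 10000L, K = cfg$K %||% 10L, seed = cfg$seed %||% 1L,
    convention = cfg$convention %||% "add_one",
    step_up = isTRUE(cfg$step_up)
  )
  if (!is.null(cfg$out)) {
    readr::write_tsv(res, cfg$out, progress = FALSE)
    return(invisible(res))
  }
  res
}
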