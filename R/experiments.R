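# Monte-Carlo experiment harness: repeated synthetic-data generation and
# testing, with empirical rejection rates and their Monte-Carlo standard
# errors collected as tidy tables.

#' Binomial confidence interval for an empirical rejection rate
#'
#' Normal-approximation interval `p +/- z * sqrt(p (1 - p) / replicates)`
#' around a nominal level, the usual yardstick for type-I-error calibration:
#' an empirical rate inside the interval is consistent with the nominal
#' level at the given replicate count.
#'
#' @param level nominal level(s).
#' @param replicates Monte-Carlo replicate count.
#' @param conf confidence (default 0.95).
#' @returns a tibble with columns `alpha`, `lower`, `upper`.
#' @examples
#' binomial_ci(c(0.05, 0.01), 10000)
#' @export
binomial_ci <- function(level, replicates, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(level * (1 - level) / replicates)
  tibble::tibble(alpha = level, lower = level - half, upper = level + half)
}

# Internal: one full replicate -> named p-values.
run_one_replicate <- function(scen, methods, scope, seeds) {
  g <- simulate_genotypes(scen$n, scen$maf_panel, seed = seeds[1L])
  ph <- simulate_trait(g, scen, seed = seeds[2L])
  part <- classify_variants(g, threshold = 0.05)
  r <- suppressWarnings(residualize(ph, g))

  restrict <- function(r, idx) {
    keep <- which(r$kept_idx %in% idx)
    out <- r
    out$S_res <- r$S_res[, keep, drop = FALSE]
    out$kept_idx <- r$kept_idx[keep]
    out$dropped_idx <- intersect(r$dropped_idx, idx)
    out
  }
  r_test <- if (scope == "rare") restrict(r, part$rare_idx) else r

  p_of <- function(method) {
    tryCatch(
      switch(method,
        tow = tow_ge_test(r_test, B = scen$B, seed = seeds[3L],
                          keep_perms = FALSE)$p_value,
        vw = vw_tow_ge_test(r, part, B = scen$B, seed = seeds[3L],
                            keep_perms = FALSE)$p_value,
        wss = wss_ge_test(r_test, g, B = scen$B, seed = seeds[3L],
                          keep_perms = FALSE)$p_value,
        cmc = suppressWarnings(
          cmc_ge_test(r_test, part, g, ph$E, B = scen$B, seed = seeds[3L],
                      keep_perms = FALSE)$p_value
        ),
        stop("unknown method: ", method)
      ),
      error = function(e) NA_real_
    )
  }
  vapply(methods, p_of, numeric(1))
}

# Internal: shared experiment engine over one scenario.
run_ge_scenario <- function(scen, methods, scope, label, verbose = FALSE) {
  set.seed(scen$seed + 2L)
  seed_mat <- matrix(sample.int(.Machine$integer.max, 3L * scen$replicates),
                     ncol = 3L)
  pvals <- matrix(NA_real_, nrow = scen$replicates, ncol = length(methods),
                  dimnames = list(NULL, methods))
  for (i in seq_len(scen$replicates)) {
    pvals[i, ] <- run_one_replicate(scen, methods, scope, seed_mat[i, ])
    if (verbose && i %% 100L == 0L) message("  replicate ", i, "/", scen$replicates)
  }
  tibble::as_tibble(pvals) |>
    dplyr::mutate(scenario = label, replicate = dplyr::row_number()) |>
    tidyr::pivot_longer(dplyr::all_of(methods),
                        names_to = "method", values_to = "p_value") |>
    dplyr::select("scenario", "replicate", "method", "p_value")
}

rates_from_pvalues <- function(pvalues, alpha_levels) {
  tidyr::crossing(pvalues, alpha = alpha_levels) |>
    dplyr::group_by(.data$scenario, .data$method, .data$alpha) |>
    dplyr::summarise(
      rate = mean(.data$p_value <= .data$alpha, na.rm = TRUE),
      replicates = sum(!is.na(.data$p_value)),
      mcse = sqrt(.data$rate * (1 - .data$rate) / .data$replicates),
      .groups = "drop"
    )
}

new_ge_experiment <- function(pvalues, alpha_levels, scenarios) {
  structure(
    list(pvalues = pvalues,
         rates = rates_from_pvalues(pvalues, alpha_levels),
         scenarios = scenarios),
    class = "ge_experiment"
  )
}

#' Type-I-error experiment under a null scenario
#'
#' Runs the full pipeline -- fresh genotypes, fresh trait, residualization,
#' permutation test(s) -- on every replicate of a null scenario and reports
#' the empirical rejection rate at each nominal level with its Monte-Carlo
#' standard error `sqrt(r (1 - r) / replicates)`.
#'
#' @param scen a null [ge_scenario] (all interaction effects zero).
#' @param methods any of `"tow"`, `"vw"`, `"wss"`, `"cmc"`.
#' @param scope `"rare"` tests only rare-variant interaction columns (the
#'   rare-variant design of the calibration study); `"both"` tests all
#'   columns (and is what VW-TOW-GE requires).
#' @param verbose print progress every 100 replicates.
#' @returns a `ge_experiment` object: `$pvalues` (tidy per-replicate
#'   p-values), `$rates` (tidy rates keyed by scenario, method, alpha).
#' @export
run_type1_experiment <- function(scen, methods = c("tow", "wss"),
                                 scope = c("rare", "both"), verbose = FALSE) {
  scope <- match.arg(scope)
  stopifnot(inherits(scen, "ge_scenario"))
  if (scen$c != 0 || scen$causal_count != 0 || scen$common_causal) {
    stop("type-I-error scenarios must have all interaction effects zero.")
  }
  pv <- run_ge_scenario(scen, methods, scope, label = "null", verbose = verbose)
  new_ge_experiment(pv, scen$alpha_levels, list(null = scen))
}

#' Power experiment over a grid of alternative scenarios
#'
#' Runs the same engine as [run_type1_experiment()] over a named list of
#' scenarios (typically a grid over the effect magnitude `c`) and returns
#' empirical power per scenario, method, and nominal level.
#'
#' @param scenarios named list of [ge_scenario] objects.
#' @inheritParams run_type1_experiment
#' @returns a `ge_experiment` object.
#' @export
run_power_experiment <- function(scenarios, methods = c("tow", "wss"),
                                 scope = c("rare", "both"), verbose = FALSE) {
  scope <- match.arg(scope)
  stopifnot(length(scenarios) >= 1, all(vapply(scenarios, inherits,
                                               logical(1), "ge_scenario")))
  if (is.null(names(scenarios))) names(scenarios) <- paste0("scenario_", seq_along(scenarios))
  pv <- purrr::imap(scenarios, function(scen, label) {
    if (verbose) message("scenario ", label)
    run_ge_scenario(scen, methods, scope, label = label, verbose = verbose)
  }) |> purrr::list_rbind()
  new_ge_experiment(pv, scenarios[[1]]$alpha_levels, scenarios)
}

#' @export
print.ge_experiment <- function(x, ...) {
  cat(sprintf("<ge_experiment> %d scenario(s), %d method(s), %d replicate p-values\n",
              length(x$scenarios), length(unique(x$pvalues$method)),
              nrow(x$pvalues)))
  print(x$rates, n = 20)
  invisible(x)
}

#' Tidy rejection-rate table of an experiment
#'
#' @param x a `ge_experiment`.
#' @param ... unused.
#' @returns tibble keyed by (`scenario`, `method`, `alpha`) with `rate`,
#'   `mcse`, `replicates`.
#' @method tidy ge_experiment
#' @export
tidy.ge_experiment <- function(x, ...) x$rates

#' @method glance ge_experiment
#' @export
glance.ge_experiment <- function(x, ...) {
  tibble::tibble(
    n_scenarios = length(x$scenarios),
    n_methods = length(unique(x$pvalues$method)),
    replicates = max(x$rates$replicates),
    B = x$scenarios[[1]]$B
  )
}

#' Rejection-rate plot for an experiment
#'
#' For a power grid whose scenarios differ in the effect magnitude `c`,
#' draws power curves (rate vs `c`, one line per method, at the smallest
#' nominal level by default); otherwise draws rates per nominal level with
#' binomial confidence bands.
#'
#' @param object a `ge_experiment`.
#' @param alpha nominal level to plot (default 0.05).
#' @param ... unused.
#' @returns a ggplot object.
#' @method autoplot ge_experiment
#' @export
autoplot.ge_experiment <- function(object, alpha = 0.05, ...) {
  level <- alpha
  rates <- dplyr::filter(object$rates, .data$alpha == level)
  cs <- vapply(object$scenarios, function(s) s$c, numeric(1))
  if (length(unique(cs)) > 1) {
    rates$c <- cs[rates$scenario]
    ggplot2::ggplot(rates, ggplot2::aes(x = .data$c, y = .data$rate,
                                        colour = .data$method)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "interaction effect magnitude c",
                    y = sprintf("empirical power (alpha = %g)", alpha),
                    colour = NULL) +
      ggplot2::ylim(0, 1) +
      ggplot2::theme_minimal()
  } else {
    ci <- binomial_ci(alpha, max(rates$replicates))
    ggplot2::ggplot(rates, ggplot2::aes(x = .data$method, y = .data$rate)) +
      ggplot2::geom_col(fill = "grey70") +
      ggplot2::geom_hline(yintercept = c(ci$lower, alpha, ci$upper),
                          linetype = c("dashed", "solid", "dashed"),
                          colour = "firebrick") +
      ggplot2::labs(x = NULL, y = sprintf("empirical rate at alpha = %g", alpha)) +
      ggplot2::theme_minimal()
  }
}
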