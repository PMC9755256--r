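#' Default sweep grids
#'
#' The default parameter sweep covers moderate-to-high ecological
#' variability (alpha_e from 0.5 to 1, five values) and zero-to-moderate
#' genetic differences (alpha_g from 0 to 0.5, six values): 30 combinations,
#' 20 replicates each, 600 runs.
#'
#' @name sweep_defaults
#' @keywords internal
NULL

default_alpha_e_grid <- function() seq(0.5, 1, length.out = 5)
default_alpha_g_grid <- function() seq(0, 0.5, by = 0.1)

run_grid <- function(grid, t_max, sigma, sites, space, threshold, progress = FALSE) {
  one <- function(alpha_e, alpha_g, S, replicate, seed, ...) {
    sim <- run_simulation(
      sim_params(
        S = S, alpha_g = alpha_g, alpha_e = alpha_e,
        t_max = t_max, sigma = sigma, seed = seed
      ),
      sites = sites, space = space
    )
    tibble::tibble(
      n_cultural = count_cultural(sim),
      n_locally_restricted = length(locally_restricted(sim$census))
    )
  }
  res <- purrr::pmap(grid, one, .progress = progress)
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  out$above_threshold <- out$n_cultural > threshold
  out
}

#' Parameter sweep over ecological and genetic variability
#'
#' Runs `run_simulation()` for every (alpha_e, alpha_g) combination and
#' replicate, with reproducible per-run seeds derived from `base_seed`.
#'
#' @param alpha_e_values,alpha_g_values Grid values in \[0, 1\]; defaults
#'   span alpha_e 0.5-1 (5 values) and alpha_g 0-0.5 (6 values), giving 600
#'   runs at 20 replicates.
#' @param S Social-mediation probability used for all runs (default 1).
#' @param replicates Runs per combination (default 20).
#' @param base_seed Master seed from which every run's seed derives.
#' @param t_max,sigma Passed to [sim_params()].
#' @param sites,space World tables.
#' @param threshold Cultural-count threshold recorded in the
#'   `above_threshold` column (default 38, the benchmark repertoire size).
#' @param progress Show a progress bar.
#' @return A tibble with one row per run: the grid columns, `seed`,
#'   `n_cultural`, `n_locally_restricted`, `above_threshold`.
#' @export
sweep_grid <- function(alpha_e_values = default_alpha_e_grid(),
                       alpha_g_values = default_alpha_g_grid(),
                       S = 1, replicates = 20, base_seed = 1,
                       t_max = 6000L, sigma = 0.05,
                       sites = site_map(), space = behaviour_space(),
                       threshold = 38, progress = FALSE) {
  if (length(alpha_e_values) < 1 || length(alpha_g_values) < 1 || replicates < 1) {
    rlang::abort("The sweep grid must be non-empty with `replicates` >= 1.",
      class = "exclusim_config_error"
    )
  }
  grid <- tidyr::expand_grid(
    alpha_e = alpha_e_values, alpha_g = alpha_g_values, S = S,
    replicate = seq_len(replicates)
  )
  set.seed(base_seed)
  grid$seed <- sample.int(.Machine$integer.max, nrow(grid))
  run_grid(grid, t_max, sigma, sites, space, threshold, progress)
}

#' Rank correlation between two columns
#'
#' Spearman rank correlation (average ranks for ties) with the asymptotic
#' t-approximation p-value, or an optional permutation p-value; Pearson is
#' available for sensitivity checks.
#'
#' @param data A data frame of pairs.
#' @param x,y Column names (default the `n` / `n_cultural` pairs produced by
#'   [correlation_experiment()]).
#' @param method "spearman" (default) or "pearson".
#' @param p_method "asymptotic" (default) or "permutation".
#' @param n_perm Number of permutations when `p_method = "permutation"`.
#' @return A one-row tibble with `method`, `p_method`, `rho`, `p_value`, `n`.
#' @export
rank_correlation <- function(data, x = "n", y = "n_cultural",
                             method = c("spearman", "pearson"),
                             p_method = c("asymptotic", "permutation"),
                             n_perm = 10000) {
  method <- match.arg(method)
  p_method <- match.arg(p_method)
  xv <- data[[x]]
  yv <- data[[y]]
  if (length(xv) < 3) {
    rlang::abort("At least 3 pairs are required.", class = "exclusim_config_error")
  }
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    rlang::abort(
      "Correlation undefined: one of the variables has zero variance.",
      class = "exclusim_degenerate_error"
    )
  }
  if (p_method == "asymptotic") {
    ct <- suppressWarnings(stats::cor.test(xv, yv, method = method, exact = FALSE))
    rho <- unname(ct$estimate)
    p <- ct$p.value
  } else {
    rho <- stats::cor(xv, yv, method = method)
    perm <- replicate(n_perm, stats::cor(xv, sample(yv), method = method))
    p <- (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1)
  }
  tibble::tibble(
    method = method, p_method = p_method, rho = rho, p_value = p,
    n = length(xv)
  )
}

#' Population size versus cultural repertoire
#'
#' Runs the simulation `runs` times, records for every site the number of
#' expressed pattern-D behaviours, pools the `runs x 6` (population size,
#' cultural count) pairs, and computes their rank correlation.
#'
#' @param runs Number of replicate simulations (>= 2; 100 reproduces the
#'   full experiment of 600 pairs).
#' @param S,alpha_e,alpha_g,t_max,sigma Simulation parameters (defaults are
#'   the benchmark condition S = 1, alpha_e = 0.8, alpha_g = 0.2).
#' @param base_seed Master seed; per-run seeds derive from it.
#' @param sites,space World tables.
#' @param progress Show a progress bar.
#' @inheritParams rank_correlation
#' @return A `culture_correlation` object: list with `pairs` (tibble `run`,
#'   `site`, `n`, `n_cultural`) and `estimate` (the [rank_correlation()]
#'   row). `tidy()` returns the pairs, `glance()` the estimate.
#' @export
correlation_experiment <- function(runs = 100, S = 1, alpha_e = 0.8, alpha_g = 0.2,
                                   t_max = 6000L, sigma = 0.05, base_seed = 1,
                                   sites = site_map(), space = behaviour_space(),
                                   method = "spearman", p_method = "asymptotic",
                                   progress = FALSE) {
  if (runs < 2) {
    rlang::abort("`runs` must be at least 2.", class = "exclusim_config_error")
  }
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max, runs)
  one <- function(r) {
    sim <- run_simulation(
      sim_params(
        S = S, alpha_g = alpha_g, alpha_e = alpha_e, t_max = t_max,
        sigma = sigma, seed = seeds[r]
      ),
      sites = sites, space = space
    )
    counts <- per_population_cultural_counts(sim$census, sim$patterns)
    dplyr::mutate(
      dplyr::inner_join(counts, sites[, c("site", "n")], by = "site"),
      run = r, .before = 1
    )
  }
  pairs <- purrr::map(seq_len(runs), one, .progress = progress) |>
    dplyr::bind_rows() |>
    dplyr::select("run", "site", "n", "n_cultural")
  structure(
    list(
      pairs = pairs,
      estimate = rank_correlation(pairs, method = method, p_method = p_method)
    ),
    class = "culture_correlation"
  )
}

#' @export
print.culture_correlation <- function(x, ...) {
  e <- x$estimate
  cat(sprintf(
    "<culture_correlation> %s rho = %.3f (p = %.3g, n = %d pairs)\n",
    e$method, e$rho, e$p_value, e$n
  ))
  invisible(x)
}

#' Effect of the social-mediation probability S
#'
#' Sweeps S at fixed ecological and genetic variability and summarises the
#' mean cultural count per S value. Lowering S removes the
#' frequency-weighting of re-innovation and is expected to lower the number
#' of pattern-D behaviours.
#'
#' @param S_values S values to sweep (default 0, 0.25, 0.5, 0.75, 1).
#' @param alpha_e,alpha_g Fixed variability parameters (defaults 0.8 / 0.2).
#' @param replicates Runs per S value (default 20).
#' @param base_seed,t_max,sigma,sites,space,progress As in [sweep_grid()].
#' @param threshold Threshold for the `above_threshold` column.
#' @return A `culture_s_effect` object: list with `rows` (one per run, as in
#'   [sweep_grid()]) and `summary` (per-S mean and sd of `n_cultural`).
#' @export
s_effect_experiment <- function(S_values = c(0, 0.25, 0.5, 0.75, 1),
                                alpha_e = 0.8, alpha_g = 0.2, replicates = 20,
                                base_seed = 1, t_max = 6000L, sigma = 0.05,
                                sites = site_map(), space = behaviour_space(),
                                threshold = 38, progress = FALSE) {
  if (length(S_values) < 1 || any(S_values < 0 | S_values > 1)) {
    rlang::abort("`S_values` must be a non-empty subset of [0, 1].",
      class = "exclusim_config_error"
    )
  }
  grid <- tidyr::expand_grid(
    alpha_e = alpha_e, alpha_g = alpha_g, S = S_values,
    replicate = seq_len(replicates)
  )
  set.seed(base_seed)
  grid$seed <- sample.int(.Machine$integer.max, nrow(grid))
  rows <- run_grid(grid, t_max, sigma, sites, space, threshold, progress)
  summary <- rows |>
    dplyr::group_by(.data$S) |>
    dplyr::summarise(
      mean_cultural = mean(.data$n_cultural),
      sd_cultural = stats::sd(.data$n_cultural),
      replicates = dplyr::n(), .groups = "drop"
    )
  structure(list(rows = rows, summary = summary), class = "culture_s_effect")
}

#' @export
print.culture_s_effect <- function(x, ...) {
  cat("<culture_s_effect> mean cultural count by S:\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}
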