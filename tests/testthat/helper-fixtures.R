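# Shared fixtures. Heavy full-length runs are computed once per test session
# and reused across test files.

the_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(the_cache[[key]])) the_cache[[key]] <- force(expr)
  the_cache[[key]]
}

# 20 full-length runs at the benchmark condition (S = 1, alpha_e = 0.8,
# alpha_g = 0.2, t_max = 6000).
benchmark_runs <- function() {
  cached("benchmark", lapply(1:20, function(s) {
    run_simulation(sim_params(S = 1, alpha_e = 0.8, alpha_g = 0.2, seed = 1000 + s))
  }))
}

# Build a one-behaviour census tibble from a vector of levels (one per site).
census_row <- function(levels, behaviour_id = 1L) {
  tibble::tibble(
    behaviour_id = behaviour_id,
    site = paste0("site_", seq_along(levels)),
    level = factor(levels, levels = c(
      "customary", "habitual", "present", "absent", "ecological_explanation"
    ))
  )
}

# Independent truth-table oracle for the A-D patterns, written directly from
# the verbal definitions (counts of per-site levels), without the precedence
# shortcut used by assign_patterns().
oracle_pattern <- function(levels) {
  n_absent <- sum(levels == "absent")
  n_eco <- sum(levels == "ecological_explanation")
  n_customary <- sum(levels == "customary")
  n_habitual <- sum(levels == "habitual")
  if (n_absent + n_eco == 0) {
    return("A")
  }
  if (n_customary + n_habitual == 0) {
    return("B")
  }
  if (n_absent == 0) {
    return("C")
  }
  "D"
}

# A propensity table in which every behaviour is fully expressible at every
# site (p_g = p_e = 1), handy for deterministic dynamics tests.
open_propensities <- function(space = behaviour_space(), sites = site_map()) {
  tibble::tibble(
    behaviour_id = rep(space$behaviour_id, each = nrow(sites)),
    site = rep(sites$site, times = nrow(space)),
    p_g = 1, p_e = 1
  )
}
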