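#' Simulation parameters
#'
#' Bundles and validates the tunable parameters of a run.
#'
#' @param S Probability that an acquisition is socially mediated/triggered,
#'   i.e. that the behaviour to (re)innovate is drawn proportionally to its
#'   current frequency in the population rather than uniformly.
#' @param alpha_g,alpha_e Probabilities that a behaviour's genetic
#'   propensity / ecological availability differs across sites
#'   (see [assign_propensities()]).
#' @param t_max Number of monthly steps to simulate (default 6000, i.e. 500
#'   years — long enough for the trait distribution to equilibrate).
#' @param sigma Standard deviation of the normal draw around `1 - state`
#'   used as innovation probability (default 0.05).
#' @param peer_noise Standard deviation of the perceptual noise on the
#'   expresser counts that weight a socially mediated draw (default 1). With
#'   noise, rarely and never-expressed behaviours keep a small chance of
#'   being re-innovated, which lets repertoires reach an equilibrium set by
#'   the propensities instead of freezing on founder behaviours. `0` gives
#'   strictly count-proportional weighting.
#' @param seed Optional integer seed; every source of randomness in
#'   [run_simulation()] derives from it.
#' @param death_onset,death_hazard,max_age,init_max_age Demographic
#'   parameters, see [demographic_step()] and [init_population()].
#' @param age_breaks Month cut-points splitting \[0, `max_age`\] into age
#'   classes for the census (default 192 and 480 months: juveniles,
#'   prime-age adults, old adults).
#' @return An object of class `sim_params`.
#' @examples
#' sim_params(S = 1, alpha_g = 0.2, alpha_e = 0.8, seed = 1)
#' @export
sim_params <- function(S = 1, alpha_g = 0, alpha_e = 0, t_max = 6000L, sigma = 0.05,
                       peer_noise = 1, seed = NULL, death_onset = 300L,
                       death_hazard = 0.01, max_age = 720L, init_max_age = 300L,
                       age_breaks = c(192L, 480L)) {
  for (p in list(S = S, alpha_g = alpha_g, alpha_e = alpha_e)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      rlang::abort("`S`, `alpha_g` and `alpha_e` must be single probabilities in [0, 1].",
        class = "exclusim_config_error"
      )
    }
  }
  if (t_max < 0) {
    rlang::abort("`t_max` must be a non-negative integer.", class = "exclusim_config_error")
  }
  if (sigma < 0 || peer_noise < 0) {
    rlang::abort("`sigma` and `peer_noise` must be non-negative.",
      class = "exclusim_config_error"
    )
  }
  structure(
    list(
      S = S, alpha_g = alpha_g, alpha_e = alpha_e, t_max = as.integer(t_max),
      sigma = sigma, peer_noise = peer_noise, seed = seed,
      death_onset = as.integer(death_onset),
      death_hazard = death_hazard, max_age = as.integer(max_age),
      init_max_age = as.integer(init_max_age), age_breaks = as.integer(age_breaks)
    ),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params> S=%g alpha_g=%g alpha_e=%g t_max=%d sigma=%g seed=%s\n",
    x$S, x$alpha_g, x$alpha_e, x$t_max, x$sigma,
    if (is.null(x$seed)) "NULL" else format(x$seed)
  ))
  invisible(x)
}

#' Social state of an agent
#'
#' The fraction of the four social sub-categories in which the agent
#' expresses at least one behaviour. An agent with one "play" behaviour and
#' nothing else has state 0.25; covering all four sub-categories gives 1.
#'
#' @param repertoire Integer vector of behaviour ids the agent expresses.
#' @param space Behaviour table from [behaviour_space()].
#' @return A value in \[0, 1\].
#' @export
social_state <- function(repertoire, space = behaviour_space()) {
  soc <- space$category == "social"
  subs <- unique(space$subcategory[soc])
  owned_subs <- space$subcategory[soc & space$behaviour_id %in% repertoire]
  sum(subs %in% owned_subs) / length(subs)
}

#' Food state of an agent
#'
#' With F fulfilled food sub-categories, of which F_Y provide nutrient Y and
#' F_Z nutrient Z, the state is (F - |F_Y - F_Z|) / C where C is the number
#' of food sub-categories: total intake rewarded, nutrient imbalance
#' penalised, normalised to \[0, 1\].
#'
#' @inheritParams social_state
#' @return A value in \[0, 1\].
#' @export
food_state <- function(repertoire, space = behaviour_space()) {
  food <- space$category == "food"
  sub_nut <- unique(space[food, c("subcategory", "nutrient")])
  owned_subs <- unique(space$subcategory[food & space$behaviour_id %in% repertoire])
  nut <- sub_nut$nutrient[sub_nut$subcategory %in% owned_subs]
  f <- length(nut)
  st <- (f - abs(sum(nut == "Y") - sum(nut == "Z"))) / nrow(sub_nut)
  min(max(st, 0), 1)
}

#' Innovation probability from a state
#'
#' One draw per state from Normal(1 - state, sigma), clamped into \[0, 1\]:
#' the fewer functions an agent already fulfils, the more likely it is to
#' attempt an innovation this month.
#'
#' @param state Numeric vector of states in \[0, 1\].
#' @param sigma Standard deviation of the draw (>= 0; `sigma = 0` returns
#'   `1 - state` exactly).
#' @return Numeric vector of probabilities, one per state.
#' @export
innovation_probability <- function(state, sigma = 0.05) {
  if (any(state < 0 | state > 1)) {
    rlang::abort("`state` must lie in [0, 1].", class = "exclusim_config_error")
  }
  if (sigma < 0) {
    rlang::abort("`sigma` must be non-negative.", class = "exclusim_config_error")
  }
  pmin(pmax(rnorm(length(state), 1 - state, sigma), 0), 1)
}

#' Select a behaviour to (re)innovate within a category
#'
#' With probability `S` the draw is socially mediated: behaviours are
#' sampled with weights `max(0, Normal(count, peer_noise))` — the observer's
#' noisy perception of how many population members currently express each
#' behaviour (frequency-weighted re-innovation; no behavioural specifics
#' are transmitted). With `peer_noise = 0` the weights are exactly
#' proportional to the counts. Otherwise, or whenever every weight is zero
#' (in particular while the whole category is unexpressed and
#' `peer_noise = 0`), the draw is uniform over the category.
#'
#' @param counts Non-negative expresser counts for the behaviours of one
#'   category, optionally named by behaviour id.
#' @param S Probability that the draw is frequency-weighted.
#' @param peer_noise Standard deviation of the perceptual noise on the
#'   counts (default 1; see [sim_params()]).
#' @return A single behaviour id (name of the chosen count, or its index if
#'   unnamed).
#' @export
select_behaviour <- function(counts, S, peer_noise = 1) {
  if (any(counts < 0)) {
    rlang::abort("`counts` must be non-negative.", class = "exclusim_config_error")
  }
  ids <- if (is.null(names(counts))) seq_along(counts) else as.integer(names(counts))
  j <- if (runif(1) < S) {
    sample_weighted(counts, peer_noise)
  } else {
    sample.int(length(counts), 1L)
  }
  ids[j]
}

# One frequency-weighted draw under noisy count perception; uniform when
# every perceived weight is zero.
sample_weighted <- function(counts, peer_noise) {
  w <- if (peer_noise > 0) pmax(rnorm(length(counts), counts, peer_noise), 0) else counts
  if (sum(w) > 0) {
    sample.int(length(counts), 1L, prob = w)
  } else {
    sample.int(length(counts), 1L)
  }
}

# Precomputed index structures for the vectorised engine. Repertoire matrix
# columns follow the row order of `space`.
space_internals <- function(space) {
  social_cols <- which(space$category == "social")
  food_cols <- which(space$category == "food")
  s_sub <- factor(space$subcategory[social_cols],
    levels = unique(space$subcategory[social_cols])
  )
  f_sub <- factor(space$subcategory[food_cols],
    levels = unique(space$subcategory[food_cols])
  )
  nut_y <- tapply(space$nutrient[food_cols], f_sub, function(x) x[1]) == "Y"
  list(
    social_cols = social_cols, food_cols = food_cols,
    sub_idx_s = as.integer(s_sub), sub_idx_f = as.integer(f_sub),
    nut_y = as.vector(nut_y),
    n_social_sub = nlevels(s_sub), n_food_sub = nlevels(f_sub)
  )
}

# Behaviour draws for k attempting agents sharing one snapshot of category
# counts: frequency-weighted under per-observer perceptual noise with
# probability S, uniform otherwise. The weighted draws are vectorised with
# the Gumbel-max trick (argmax of log-weight plus standard Gumbel noise is
# an exact weighted sample); an all-zero perceived row degenerates to a
# uniform random tie-break.
pick_category <- function(k, counts, S, peer_noise) {
  weighted <- runif(k) < S
  beh <- integer(k)
  nw <- sum(weighted)
  m <- length(counts)
  if (nw > 0L) {
    if (peer_noise > 0) {
      w <- pmax(rnorm(nw * m, rep(counts, each = nw), peer_noise), 0)
      gumbel <- -log(-log(runif(nw * m)))
      beh[weighted] <- max.col(matrix(log(w) + gumbel, nw, m), ties.method = "random")
    } else if (sum(counts) > 0) {
      beh[weighted] <- sample.int(m, nw, replace = TRUE, prob = counts)
    } else {
      beh[weighted] <- sample.int(m, nw, replace = TRUE)
    }
  }
  if (k - nw > 0L) {
    beh[!weighted] <- sample.int(m, k - nw, replace = TRUE)
  }
  beh
}

# Core of one synchronous innovation step, shared by the exported
# `innovation_step()` and the maintained-state fast loop (identical RNG draw
# order in both). Inputs: per-agent states, per-behaviour expresser counts
# snapshotted at entry, per-behaviour acceptance gates at the site, and the
# ownership test. Returns, per agent, which category (if any) gained which
# behaviour this month.
step_decisions <- function(n, st_s, st_f, cnt_s, cnt_f, gate_social, gate_food,
                           owned_social, owned_food, S, sigma, peer_noise) {
  # runif(n) < p is unaffected by clamping p into [0, 1], so the normal draw
  # is used unclamped here.
  p_s <- rnorm(n, 1 - st_s, sigma)
  p_f <- rnorm(n, 1 - st_f, sigma)
  try_s <- runif(n) < p_s
  try_f <- runif(n) < p_f

  add_s <- logical(n)
  beh_s <- integer(n)
  idx <- which(try_s)
  if (length(idx)) {
    b <- pick_category(length(idx), cnt_s, S, peer_noise)
    ok <- runif(length(idx)) < gate_social[b] & !owned_social(idx, b)
    add_s[idx] <- ok
    beh_s[idx] <- b
  }

  add_f <- logical(n)
  beh_f <- integer(n)
  idx <- which(try_f)
  if (length(idx)) {
    b <- pick_category(length(idx), cnt_f, S, peer_noise)
    ok <- runif(length(idx)) < gate_food[b] & !owned_food(idx, b)
    add_f[idx] <- ok
    beh_f[idx] <- b
  }

  # Random category order per agent; the first successful new addition ends
  # the agent's turn, so at most one behaviour per agent per month.
  social_first <- runif(n) < 0.5
  list(
    do_s = add_s & (social_first | !add_f),
    do_f = add_f & (!social_first | !add_s),
    beh_s = beh_s, beh_f = beh_f
  )
}

#' One innovation step for a population
#'
#' Processes every agent once against a shared snapshot of behaviour
#' frequencies: each agent may attempt one social and one food acquisition
#' (in random order), each attempt fires with the state-dependent
#' innovation probability, the behaviour is drawn by [select_behaviour()]
#' semantics, and the addition passes a propensity gate (p_g for social
#' behaviours, p_g * p_e for food). The first successful addition of a new
#' behaviour ends the agent's turn; failed gates or already-owned draws
#' consume the attempt without change.
#'
#' @param pop Population from [init_population()] whose `site` matches a
#'   site in `propensities`.
#' @param propensities Long propensity table from [assign_propensities()].
#' @param space Behaviour table from [behaviour_space()].
#' @param params A [sim_params()] object (uses `S` and `sigma`).
#' @return The updated population.
#' @export
innovation_step <- function(pop, propensities, space, params) {
  site <- pop$site
  if (is.na(site)) {
    sites_present <- unique(propensities$site)
    if (length(sites_present) != 1L) {
      rlang::abort("`pop$site` is NA and `propensities` covers several sites.",
        class = "exclusim_config_error"
      )
    }
    site <- sites_present
  }
  pr <- propensities[propensities$site == site, ]
  pr <- pr[match(space$behaviour_id, pr$behaviour_id), ]
  si <- space_internals(space)
  gate_social <- pr$p_g[si$social_cols]
  gate_food <- pr$p_g[si$food_cols] * pr$p_e[si$food_cols]

  repm <- pop$rep
  n <- nrow(repm)
  rep_s <- repm[, si$social_cols, drop = FALSE]
  rep_f <- repm[, si$food_cols, drop = FALSE]
  sub_s <- rowsum_cols(rep_s, si$sub_idx_s, si$n_social_sub)
  sub_f <- rowsum_cols(rep_f, si$sub_idx_f, si$n_food_sub)

  dec <- step_decisions(
    n,
    st_s = rowSums(sub_s > 0L) / si$n_social_sub,
    st_f = food_state_from_counts(sub_f, si),
    cnt_s = colSums(rep_s), cnt_f = colSums(rep_f),
    gate_social = gate_social, gate_food = gate_food,
    owned_social = function(i, b) rep_s[cbind(i, b)],
    owned_food = function(i, b) rep_f[cbind(i, b)],
    S = params$S, sigma = params$sigma, peer_noise = params$peer_noise
  )
  if (any(dec$do_s)) {
    repm[cbind(which(dec$do_s), si$social_cols[dec$beh_s[dec$do_s]])] <- TRUE
  }
  if (any(dec$do_f)) {
    repm[cbind(which(dec$do_f), si$food_cols[dec$beh_f[dec$do_f]])] <- TRUE
  }
  pop$rep <- repm
  pop
}

# Per-agent fulfilled-behaviour counts per sub-category: agents x subcats.
rowsum_cols <- function(m, sub_idx, k) {
  out <- matrix(0L, nrow(m), k)
  for (j in seq_len(ncol(m))) {
    out[, sub_idx[j]] <- out[, sub_idx[j]] + m[, j]
  }
  out
}

# (F - |F_Y - F_Z|) / C from an agents x food-subcategory count matrix.
food_state_from_counts <- function(sub_f, si) {
  ff <- sub_f > 0L
  f_tot <- rowSums(ff)
  f_y <- rowSums(ff[, si$nut_y, drop = FALSE])
  (f_tot - abs(2 * f_y - f_tot)) / si$n_food_sub
}

# Full trajectory of one site with incrementally maintained bookkeeping:
# repertoire matrix, per-agent sub-category counts and per-behaviour
# expresser counts. RNG draw order per step matches demographic_step()
# followed by innovation_step() exactly.
simulate_site <- function(n, site, gate_social, gate_food, si, params,
                          trace = NULL, space_ids = NULL) {
  n_beh <- length(si$social_cols) + length(si$food_cols)
  age <- sample.int(params$init_max_age, n, replace = TRUE) - 1L
  repm <- matrix(FALSE, n, n_beh)
  sub_s <- matrix(0L, n, si$n_social_sub)
  sub_f <- matrix(0L, n, si$n_food_sub)
  cnt_s <- numeric(length(si$social_cols))
  cnt_f <- numeric(length(si$food_cols))
  onset <- params$death_onset
  hazard <- params$death_hazard
  cap <- params$max_age
  traces <- list()

  t <- 0L
  while (t < params$t_max) {
    t <- t + 1L
    # demography
    age <- age + 1L
    dead <- (age >= onset & runif(n) < hazard) | age > cap
    if (any(dead)) {
      w <- which(dead)
      age[w] <- 0L
      if (length(w) == 1L) {
        cnt_s <- cnt_s - repm[w, si$social_cols]
        cnt_f <- cnt_f - repm[w, si$food_cols]
      } else {
        cnt_s <- cnt_s - colSums(repm[w, si$social_cols, drop = FALSE])
        cnt_f <- cnt_f - colSums(repm[w, si$food_cols, drop = FALSE])
      }
      repm[w, ] <- FALSE
      sub_s[w, ] <- 0L
      sub_f[w, ] <- 0L
    }

    # innovation
    dec <- step_decisions(
      n,
      st_s = rowSums(sub_s > 0L) / si$n_social_sub,
      st_f = food_state_from_counts(sub_f, si),
      cnt_s = cnt_s, cnt_f = cnt_f,
      gate_social = gate_social, gate_food = gate_food,
      owned_social = function(i, b) repm[cbind(i, si$social_cols[b])],
      owned_food = function(i, b) repm[cbind(i, si$food_cols[b])],
      S = params$S, sigma = params$sigma, peer_noise = params$peer_noise
    )
    if (any(dec$do_s)) {
      w <- which(dec$do_s)
      b <- dec$beh_s[w]
      repm[cbind(w, si$social_cols[b])] <- TRUE
      sub <- cbind(w, si$sub_idx_s[b])
      sub_s[sub] <- sub_s[sub] + 1L
      cnt_s <- cnt_s + tabulate(b, length(cnt_s))
    }
    if (any(dec$do_f)) {
      w <- which(dec$do_f)
      b <- dec$beh_f[w]
      repm[cbind(w, si$food_cols[b])] <- TRUE
      sub <- cbind(w, si$sub_idx_f[b])
      sub_f[sub] <- sub_f[sub] + 1L
      cnt_f <- cnt_f + tabulate(b, length(cnt_f))
    }
    if (!is.null(trace) && t %% trace == 0L) {
      traces[[length(traces) + 1L]] <- tibble::tibble(
        step = t, site = site, behaviour_id = space_ids,
        count = colSums(repm)
      )
    }
  }

  pop <- structure(list(site = site, age = age, rep = repm), class = "culture_pop")
  if (is.null(trace)) pop else list(pop = pop, trace = traces)
}

#' Run a full simulation
#'
#' Builds the propensity tables once, then iterates `t_max` monthly steps of
#' demography followed by innovation over all populations. Populations are
#' fully independent: each site runs on its own RNG stream seeded from the
#' master seed, so no information of any kind crosses sites. The final
#' populations are censused with the method of exclusion.
#'
#' @param params A [sim_params()] object.
#' @param sites Site table from [site_map()].
#' @param space Behaviour table from [behaviour_space()].
#' @param trace_every Optional integer k: record per-behaviour expresser
#'   counts every k steps (in `$trace`). `NULL` (default) disables tracing;
#'   tracing always uses the R engine.
#' @param engine `"cpp"` (default) for the compiled site loop, `"r"` for
#'   the reference R implementation. The two implement the same model and
#'   agree in distribution; the R engine additionally matches
#'   [demographic_step()]/[innovation_step()] draw for draw, which is how
#'   the engines are cross-validated in the test suite.
#' @return An object of class `culture_sim` with elements `params`, `sites`,
#'   `space`, `propensities`, `populations` (list of final populations),
#'   `census` (behaviour x site levels), `patterns` (A-D per behaviour) and
#'   optionally `trace`. Use [tidy()], [glance()] and [autoplot()] on it.
#' @examples
#' sim <- run_simulation(sim_params(
#'   S = 1, alpha_e = 0.8, alpha_g = 0.2,
#'   t_max = 120, seed = 1
#' ))
#' glance(sim)
#' @export
run_simulation <- function(params = sim_params(), sites = site_map(),
                           space = behaviour_space(), trace_every = NULL,
                           engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (!is.null(trace_every)) engine <- "r"
  validate_site_map(sites)
  if (!is.null(params$seed)) set.seed(params$seed)
  propensities <- assign_propensities(space, sites, params$alpha_g, params$alpha_e)
  mats <- propensity_matrices(propensities, sites)
  ord <- match(space$behaviour_id, as.integer(rownames(mats$p_g)))
  p_g <- mats$p_g[ord, , drop = FALSE]
  p_e <- mats$p_e[ord, , drop = FALSE]
  site_seeds <- sample.int(.Machine$integer.max, nrow(sites))
  si <- space_internals(space)

  pops <- vector("list", nrow(sites))
  traces <- list()
  for (j in seq_len(nrow(sites))) {
    set.seed(site_seeds[j])
    if (engine == "cpp") {
      raw <- .sim_site_cpp(
        n = sites$n[j], t_max = params$t_max,
        gate_social = p_g[si$social_cols, j],
        gate_food = p_g[si$food_cols, j] * p_e[si$food_cols, j],
        sub_idx_s = si$sub_idx_s, sub_idx_f = si$sub_idx_f,
        nut_y = si$nut_y,
        n_social_sub = si$n_social_sub, n_food_sub = si$n_food_sub,
        S = params$S, sigma = params$sigma, peer_noise = params$peer_noise,
        death_onset = params$death_onset, death_hazard = params$death_hazard,
        max_age = params$max_age, init_max_age = params$init_max_age
      )
      pops[[j]] <- structure(
        list(site = sites$site[j], age = raw$age, rep = raw$rep),
        class = "culture_pop"
      )
    } else {
      out <- simulate_site(
        n = sites$n[j], site = sites$site[j],
        gate_social = p_g[si$social_cols, j],
        gate_food = p_g[si$food_cols, j] * p_e[si$food_cols, j],
        si = si, params = params,
        trace = trace_every, space_ids = space$behaviour_id
      )
      if (is.null(trace_every)) {
        pops[[j]] <- out
      } else {
        pops[[j]] <- out$pop
        traces <- c(traces, out$trace)
      }
    }
  }

  census <- census_from_populations(pops, sites, space, p_e, params$age_breaks)
  res <- list(
    params = params, sites = sites, space = space, propensities = propensities,
    populations = pops, census = census, patterns = assign_patterns(census)
  )
  if (length(traces)) res$trace <- dplyr::bind_rows(traces)
  structure(res, class = "culture_sim")
}

#' @export
print.culture_sim <- function(x, ...) {
  counts <- table(x$patterns$pattern)
  cat(sprintf(
    "<culture_sim> %d behaviours x %d sites (S=%g, alpha_g=%g, alpha_e=%g, t_max=%d)\n",
    nrow(x$space), nrow(x$sites), x$params$S, x$params$alpha_g,
    x$params$alpha_e, x$params$t_max
  ))
  cat(sprintf(
    "  patterns: A=%d B=%d C=%d D=%d  (cultural = %d)\n",
    counts["A"], counts["B"], counts["C"], counts["D"], counts["D"]
  ))
  invisible(x)
}
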