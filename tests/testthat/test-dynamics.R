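space64 <- behaviour_space()

test_that("social state is the fraction of fulfilled social sub-categories", {
  expect_equal(social_state(integer(0), space64), 0)
  # one 'play' behaviour fulfils one of four functions
  expect_equal(social_state(1L, space64), 0.25)
  # several behaviours in the same sub-category still count once
  expect_equal(social_state(c(1L, 2L, 3L), space64), 0.25)
  # one behaviour in each sub-category saturates the state
  expect_equal(social_state(c(1L, 9L, 17L, 25L), space64), 1)
  # food behaviours do not contribute
  expect_equal(social_state(c(1L, 33L, 40L), space64), 0.25)
})

test_that("food state rewards coverage and penalises nutrient imbalance", {
  expect_equal(food_state(integer(0), space64), 0)
  first_of_each <- space64 |>
    dplyr::filter(category == "food") |>
    dplyr::distinct(subcategory, .keep_all = TRUE)
  # all ten sub-categories fulfilled: 5 Y and 5 Z, perfectly balanced
  expect_equal(food_state(first_of_each$behaviour_id, space64), 1)
  # a single Y sub-category: (1 - |1 - 0|) / 10 = 0
  y1 <- first_of_each$behaviour_id[first_of_each$nutrient == "Y"][1]
  z1 <- first_of_each$behaviour_id[first_of_each$nutrient == "Z"][1]
  expect_equal(food_state(y1, space64), 0)
  # one Y plus one Z: (2 - 0) / 10 = 0.2
  expect_equal(food_state(c(y1, z1), space64), 0.2)
  # social behaviours do not contribute
  expect_equal(food_state(c(1L, y1, z1), space64), 0.2)
})

test_that("innovation probability is Normal(1 - state, sigma) clamped to [0, 1]", {
  # zero-variance limit is exact
  expect_equal(innovation_probability(0.25, sigma = 0), 0.75)
  expect_equal(innovation_probability(c(0, 1), sigma = 0), c(1, 0))
  set.seed(1)
  draws <- innovation_probability(rep(0.5, 2000), sigma = 0.2)
  expect_true(all(draws >= 0 & draws <= 1))
  expect_lt(abs(mean(draws) - 0.5), 0.02)
  # low state centres the draw near certainty
  set.seed(2)
  expect_gt(mean(innovation_probability(rep(0, 500), sigma = 0.05)), 0.9)
  expect_error(innovation_probability(1.5), class = "exclusim_config_error")
})

test_that("behaviour selection is frequency-weighted under S, uniform otherwise", {
  counts <- c(3, 1, rep(0, 30))
  # S = 1 with exact (noise-free) weighting: proportional sampling, and
  # zero-count behaviours are unreachable
  set.seed(1)
  picks <- replicate(4000, select_behaviour(counts, S = 1, peer_noise = 0))
  expect_true(all(picks %in% 1:2))
  expect_lt(abs(mean(picks == 1) - 0.75), 0.03)
  # S = 0: uniform over the whole category
  set.seed(2)
  picks <- replicate(8000, select_behaviour(counts, S = 0, peer_noise = 0))
  expect_gt(suppressWarnings(chisq.test(tabulate(picks, 32))$p.value), 0.001)
  # S = 1 with all counts zero: uniform fallback
  set.seed(3)
  picks <- replicate(4000, select_behaviour(rep(0, 8), S = 1, peer_noise = 0))
  expect_gt(suppressWarnings(chisq.test(tabulate(picks, 8))$p.value), 0.001)
  # perceptual noise leaks probability to unexpressed behaviours
  set.seed(4)
  picks <- replicate(4000, select_behaviour(counts, S = 1, peer_noise = 1))
  expect_gt(mean(picks > 2), 0.05)
  expect_gt(mean(picks == 1), mean(picks == 2))
  # named counts return behaviour ids
  set.seed(5)
  expect_true(select_behaviour(c(`40` = 2, `41` = 1), S = 1) %in% c(40L, 41L))
  expect_error(select_behaviour(c(-1, 2), 1), class = "exclusim_config_error")
})

test_that("propensity gates are absolute and one behaviour per agent per month", {
  sites <- site_map()
  prop <- open_propensities(space64, sites)
  # zero genetic propensity for behaviour 5 everywhere
  prop$p_g[prop$behaviour_id == 5] <- 0
  # zero ecological availability for food behaviour 40 everywhere
  prop$p_e[prop$behaviour_id == 40] <- 0
  params <- sim_params(S = 1, t_max = 0)
  set.seed(1)
  pop <- init_population(40, site = "site_1")
  for (t in 1:100) {
    before <- rowSums(pop$rep)
    pop <- innovation_step(pop, prop, space64, params)
    # at most one new behaviour per agent per step
    expect_true(all(rowSums(pop$rep) - before <= 1))
  }
  expect_gt(sum(pop$rep), 0)
  expect_false(any(pop$rep[, 5]))
  expect_false(any(pop$rep[, 40]))
  # repertoires only grow through innovation steps
  set.seed(2)
  pop2 <- init_population(10, site = "site_1")
  pop2$rep[, 7] <- TRUE
  stepped <- innovation_step(pop2, prop, space64, params)
  expect_true(all(stepped$rep[, 7]))
})

test_that("simulations are deterministic given a seed, in both engines", {
  p <- sim_params(S = 1, alpha_e = 0.8, alpha_g = 0.2, t_max = 300, seed = 11)
  for (eng in c("cpp", "r")) {
    a <- run_simulation(p, engine = eng)
    b <- run_simulation(p, engine = eng)
    expect_identical(a$census, b$census)
    expect_identical(a$populations, b$populations)
  }
})

test_that("a zero-length run leaves every repertoire empty and nothing cultural", {
  sim <- run_simulation(sim_params(t_max = 0, seed = 1))
  expect_true(all(vapply(sim$populations, function(p) !any(p$rep), logical(1))))
  expect_true(all(sim$census$level %in% c("absent", "ecological_explanation")))
  expect_equal(count_cultural(sim), 0)
})

test_that("the R engine replays exactly through the exported step functions", {
  p <- sim_params(S = 1, alpha_e = 0.8, alpha_g = 0.2, t_max = 150, seed = 7)
  sim <- run_simulation(p, engine = "r")
  set.seed(7)
  prop <- assign_propensities(sim$space, sim$sites, p$alpha_g, p$alpha_e)
  site_seeds <- sample.int(.Machine$integer.max, 6)
  for (j in c(1L, 4L)) {
    set.seed(site_seeds[j])
    pop <- init_population(sim$sites$n[j], 64, p$init_max_age, sim$sites$site[j])
    for (t in 1:150) {
      pop <- demographic_step(pop)
      pop <- innovation_step(pop, prop, sim$space, p)
    }
    expect_identical(pop$rep, sim$populations[[j]]$rep)
    expect_identical(pop$age, sim$populations[[j]]$age)
  }
})

test_that("compiled and reference engines agree in distribution", {
  p <- function(s) sim_params(S = 1, alpha_e = 0.8, alpha_g = 0.2, t_max = 800, seed = s)
  stats_for <- function(eng) {
    out <- vapply(1:8, function(s) {
      sim <- run_simulation(p(s), engine = eng)
      c(
        count_cultural(sim),
        mean(vapply(sim$populations, function(q) mean(rowSums(q$rep)), numeric(1)))
      )
    }, numeric(2))
    rowMeans(out)
  }
  r_stats <- stats_for("r")
  c_stats <- stats_for("cpp")
  # same model, different RNG consumption: means must be close, not identical
  expect_lt(abs(r_stats[1] - c_stats[1]), 6)
  expect_lt(abs(r_stats[2] - c_stats[2]), 2)
})

test_that("sites evolve independently: perturbing one site leaves the others unchanged", {
  p <- sim_params(S = 1, alpha_e = 0.8, alpha_g = 0.2, t_max = 250, seed = 21)
  sites <- site_map()
  sites2 <- sites
  sites2$n[3] <- 12L
  a <- run_simulation(p, sites = sites)
  b <- run_simulation(p, sites = sites2)
  for (j in c(1, 2, 4, 5, 6)) {
    expect_identical(a$populations[[j]]$rep, b$populations[[j]]$rep)
  }
  expect_false(identical(dim(a$populations[[3]]$rep), dim(b$populations[[3]]$rep)))
})

test_that("with exact weighting and S = 1, an extinct behaviour cannot re-enter", {
  sim <- run_simulation(
    sim_params(
      S = 1, alpha_e = 0, alpha_g = 0, t_max = 800, sigma = 0.05,
      peer_noise = 0, seed = 31
    ),
    trace_every = 25
  )
  tr <- sim$trace |>
    dplyr::left_join(sim$space[, c("behaviour_id", "category")], by = "behaviour_id")
  totals <- tr |>
    dplyr::summarise(category_total = sum(count), .by = c("site", "category", "step"))
  viol <- tr |>
    dplyr::left_join(totals, by = c("site", "category", "step")) |>
    dplyr::arrange(site, behaviour_id, step) |>
    dplyr::group_by(site, behaviour_id) |>
    dplyr::summarise(
      # once the count is zero while the category is expressed, it must stay zero
      reentered = {
        dead <- which(count == 0 & category_total > 0)
        length(dead) > 0 && any(count[seq(min(dead), dplyr::n())] > 0)
      },
      .groups = "drop"
    )
  expect_false(any(viol$reentered))
})

test_that("repertoire size increases across age classes in a long run", {
  sim <- benchmark_runs()[[1]]
  by_class <- dplyr::bind_rows(lapply(sim$populations, function(p) {
    tibble::tibble(
      class = findInterval(p$age, c(192, 480)),
      size = rowSums(p$rep)
    )
  })) |>
    dplyr::group_by(class) |>
    dplyr::summarise(mean_size = mean(size))
  expect_equal(by_class$class, 0:2)
  expect_true(all(diff(by_class$mean_size) > 0))
})
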