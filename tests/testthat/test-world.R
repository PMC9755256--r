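test_that("behaviour space has the documented structure", {
  space <- behaviour_space()
  expect_equal(nrow(space), 64)
  expect_equal(sum(space$category == "social"), 32)
  expect_equal(sum(space$category == "food"), 32)
  expect_equal(space$behaviour_id, 1:64)

  social <- dplyr::count(space[space$category == "social", ], subcategory)
  expect_equal(nrow(social), 4)
  expect_true(all(social$n == 8))
  expect_true(all(space$nutrient[space$category == "social"] == "none"))

  food <- space[space$category == "food", ] |>
    dplyr::distinct(subcategory, nutrient)
  expect_equal(nrow(food), 10)
  expect_equal(sum(food$nutrient == "Y"), 5)
  expect_equal(sum(food$nutrient == "Z"), 5)
  sizes <- dplyr::count(space[space$category == "food", ], subcategory)$n
  expect_equal(sum(sizes), 32)
})

test_that("behaviour space rejects malformed food structures", {
  expect_error(
    behaviour_space(tibble::tibble(size = c(16, 15), nutrient = c("Y", "Z"))),
    class = "exclusim_config_error"
  )
  expect_error(
    behaviour_space(tibble::tibble(size = 32, nutrient = "Y")),
    class = "exclusim_config_error"
  )
  # custom but valid structure is accepted
  space <- behaviour_space(tibble::tibble(size = c(20, 12), nutrient = c("Z", "Y")))
  expect_equal(dplyr::n_distinct(space$subcategory[space$category == "food"]), 2)
})

test_that("gradient probabilities rescale distances with exact endpoints", {
  sites <- site_map()
  # point on a site: that site gets exactly 1
  p <- gradient_probabilities(c(sites$x[1], sites$y[1]), sites)
  expect_equal(unname(p[1]), 1)
  # the farthest site gets exactly 0, everything lies in [0, 1]
  set.seed(1)
  for (i in 1:20) {
    pt <- c(runif(1, -20, 40), runif(1, -10, 10))
    p <- gradient_probabilities(pt, sites)
    d <- sqrt((sites$x - pt[1])^2 + (sites$y - pt[2])^2)
    expect_equal(unname(p), (max(d) - d) / (max(d) - min(d)))
    expect_equal(sum(p == 0), 1) # unique farthest site for generic points
    expect_equal(sum(p == 1), 1) # and a unique nearest site at exactly 1
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(unname(which.max(p)), which.min(d))
  }
  # two sites equidistant from the point get identical probabilities
  sym <- tibble::tibble(
    site = c("a", "b", "c"), x = c(-1, 1, 0), y = c(0, 0, 5), n = c(5L, 5L, 5L)
  )
  p <- gradient_probabilities(c(0, 0), sym)
  expect_equal(unname(p["a"]), unname(p["b"]))
  expect_error(gradient_probabilities(c(Inf, 0), sites), class = "exclusim_config_error")
})

test_that("propensity assignment honours alpha and fixes social availability at 1", {
  space <- behaviour_space()
  sites <- site_map()

  set.seed(1)
  flat <- assign_propensities(space, sites, alpha_g = 0, alpha_e = 0)
  per_beh <- flat |>
    dplyr::group_by(behaviour_id) |>
    dplyr::summarise(
      g_const = dplyr::n_distinct(p_g) == 1,
      e_const = dplyr::n_distinct(p_e) == 1
    )
  expect_true(all(per_beh$g_const))
  expect_true(all(per_beh$e_const))

  set.seed(2)
  grad <- assign_propensities(space, sites, alpha_g = 1, alpha_e = 1)
  per_beh <- grad |>
    dplyr::group_by(behaviour_id) |>
    dplyr::summarise(has0 = any(p_g == 0), has1 = any(p_g == 1))
  # every gradient row spans the exact endpoints 0 and 1
  expect_true(all(per_beh$has0))
  expect_true(all(per_beh$has1))
  food_ids <- space$behaviour_id[space$category == "food"]
  e_rows <- grad[grad$behaviour_id %in% food_ids, ] |>
    dplyr::group_by(behaviour_id) |>
    dplyr::summarise(has0 = any(p_e == 0), has1 = any(p_e == 1))
  expect_true(all(e_rows$has0))
  expect_true(all(e_rows$has1))

  # social behaviours keep p_e = 1 whatever alpha_e
  expect_true(all(grad$p_e[!grad$behaviour_id %in% food_ids] == 1))

  # same seed, same table
  set.seed(99)
  a <- assign_propensities(space, sites, 0.3, 0.7)
  set.seed(99)
  b <- assign_propensities(space, sites, 0.3, 0.7)
  expect_identical(a, b)

  expect_error(assign_propensities(space, sites, -0.1, 0), class = "exclusim_config_error")
})

test_that("site-constant rows occur with frequency about 1 - alpha", {
  space <- behaviour_space()
  sites <- site_map()
  set.seed(7)
  n_gradient <- 0
  for (i in 1:5) {
    tab <- assign_propensities(space, sites, alpha_g = 0.5, alpha_e = 0)
    n_gradient <- n_gradient + sum(
      (tab |> dplyr::group_by(behaviour_id) |>
        dplyr::summarise(v = dplyr::n_distinct(p_g) > 1))$v
    )
  }
  # 320 rows at alpha = 0.5: binomial(320, 0.5), +-4 sd band
  expect_gt(n_gradient, 160 - 4 * sqrt(320 * 0.25))
  expect_lt(n_gradient, 160 + 4 * sqrt(320 * 0.25))
})

test_that("world configuration files round-trip sites and food structure", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "sites:",
    "  - {site: west, x: 0, y: 0, n: 10}",
    "  - {site: east, x: 5, y: 1, n: 30}",
    "food_structure:",
    "  - {size: 16, nutrient: Y}",
    "  - {size: 16, nutrient: Z}"
  ), cfg)
  world <- read_world_config(cfg)
  expect_equal(world$sites$site, c("west", "east"))
  expect_equal(world$sites$n, c(10L, 30L))
  space <- behaviour_space(world$food_structure)
  expect_equal(dplyr::n_distinct(space$subcategory[space$category == "food"]), 2)

  # defaults fill in when the file is partial
  cfg2 <- tempfile(fileext = ".yaml")
  writeLines("{}", cfg2)
  world2 <- read_world_config(cfg2)
  expect_equal(world2$sites$n, c(20L, 42L, 49L, 76L, 50L, 95L))
})

test_that("propensity tables export to CSV", {
  set.seed(3)
  tab <- assign_propensities(behaviour_space(), site_map(), 0.5, 0.5)
  f <- tempfile(fileext = ".csv")
  write_propensities(tab, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(nrow(back), 64 * 6)
  expect_equal(back$p_g, tab$p_g)
})
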