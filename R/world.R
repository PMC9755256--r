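#' Default site table
#'
#' Six populations at fixed relative planar positions with fixed sizes. The
#' default layout approximates the west-to-east arrangement of six well-known
#' ape field sites (two West African, four East African), with population
#' sizes of 20, 42, 49, 76, 50 and 95 individuals. Coordinates are arbitrary
#' planar units: only relative distances matter, since genetic and ecological
#' gradients are built from distances between a random point and each site.
#'
#' @return A tibble with columns `site` (label), `x`, `y` (planar
#'   coordinates) and `n` (population size).
#' @examples
#' site_map()
#' @export
site_map <- function() {
  tibble::tibble(
    site = paste0("site_", 1:6),
    x = c(-8.5, -7.3, 29.6, 29.9, 30.4, 31.6),
    y = c(7.6, 5.9, -4.7, -6.1, 0.6, 1.7),
    n = c(20L, 42L, 49L, 76L, 50L, 95L)
  )
}

validate_site_map <- function(sites, call = rlang::caller_env()) {
  if (!is.data.frame(sites) || !all(c("site", "x", "y", "n") %in% names(sites))) {
    rlang::abort("`sites` must be a data frame with columns site, x, y, n.",
      class = "exclusim_config_error", call = call
    )
  }
  if (anyDuplicated(sites[, c("x", "y")])) {
    rlang::abort("No two sites may share identical coordinates.",
      class = "exclusim_config_error", call = call
    )
  }
  if (any(sites$n < 1)) {
    rlang::abort("Every site needs a population size of at least 1.",
      class = "exclusim_config_error", call = call
    )
  }
  invisible(sites)
}

#' Default food sub-category structure
#'
#' Ten food sub-categories with sizes 8, 5, 4, 4, 3, 2, 2, 2, 1, 1 (summing
#' to 32 behaviours) and nutrients alternating Y, Z, Y, Z, ... so that five
#' sub-categories provide each nutrient. The structure is a configurable
#' default: any table whose sizes sum to 32 with at least one sub-category
#' per nutrient is accepted by [behaviour_space()].
#'
#' @return A tibble with columns `size` and `nutrient`.
#' @export
default_food_structure <- function() {
  tibble::tibble(
    size = c(8L, 5L, 4L, 4L, 3L, 2L, 2L, 2L, 1L, 1L),
    nutrient = rep(c("Y", "Z"), 5)
  )
}

#' Build the latent behaviour space
#'
#' The latent repertoire holds 64 behaviours: 32 social behaviours in four
#' sub-categories ("play", "display", "groom", "courtship") of eight
#' behaviours each, and 32 food-related behaviours in configurable
#' sub-categories, each providing one of two nutrients, Y or Z. By
#' convention ids 1-32 are social and 33-64 are food-related.
#'
#' @param food_structure A data frame with columns `size` (behaviours per
#'   food sub-category, summing to 32) and `nutrient` ("Y" or "Z"; at least
#'   one sub-category of each). Defaults to [default_food_structure()].
#' @return A tibble with one row per behaviour and columns `behaviour_id`,
#'   `category` ("social"/"food"), `subcategory` and `nutrient`
#'   ("Y"/"Z"/"none").
#' @examples
#' space <- behaviour_space()
#' dplyr::count(space, category)
#' @export
behaviour_space <- function(food_structure = default_food_structure()) {
  if (!is.data.frame(food_structure) ||
    !all(c("size", "nutrient") %in% names(food_structure))) {
    rlang::abort("`food_structure` needs columns `size` and `nutrient`.",
      class = "exclusim_config_error"
    )
  }
  sizes <- as.integer(food_structure$size)
  nutrients <- as.character(food_structure$nutrient)
  if (any(sizes < 1L) || sum(sizes) != 32L) {
    rlang::abort("Food sub-category sizes must be >= 1 and sum to 32.",
      class = "exclusim_config_error"
    )
  }
  if (!all(nutrients %in% c("Y", "Z")) ||
    !all(c("Y", "Z") %in% nutrients)) {
    rlang::abort(
      "Food sub-categories must use nutrients \"Y\" and \"Z\", with at least one of each.",
      class = "exclusim_config_error"
    )
  }
  social <- tibble::tibble(
    behaviour_id = 1:32,
    category = "social",
    subcategory = rep(c("play", "display", "groom", "courtship"), each = 8),
    nutrient = "none"
  )
  food <- tibble::tibble(
    behaviour_id = 33:64,
    category = "food",
    subcategory = rep(sprintf("food_%02d", seq_along(sizes)), times = sizes),
    nutrient = rep(nutrients, times = sizes)
  )
  dplyr::bind_rows(social, food)
}

#' Distance-gradient probabilities for a random point
#'
#' Rescales the Euclidean distances from `point` to each site linearly into
#' \[0, 1\] probabilities: the nearest site gets exactly 1, the farthest
#' exactly 0 (the behaviour cannot be expressed there), intermediate sites
#' fall in between as p = (d_max - d) / (d_max - d_min).
#'
#' @param point Numeric length-2 vector, planar coordinates.
#' @param sites A site table as from [site_map()].
#' @return Numeric vector of probabilities, one per site, named by site.
#' @examples
#' s <- site_map()
#' gradient_probabilities(c(s$x[1], s$y[1]), s) # site 1 gets exactly 1
#' @export
gradient_probabilities <- function(point, sites = site_map()) {
  validate_site_map(sites)
  if (!is.numeric(point) || length(point) != 2L || !all(is.finite(point))) {
    rlang::abort("`point` must be a finite numeric vector of length 2.",
      class = "exclusim_config_error"
    )
  }
  d <- sqrt((sites$x - point[1])^2 + (sites$y - point[2])^2)
  span <- max(d) - min(d)
  p <- if (span > 0) (max(d) - d) / span else rep(0.5, length(d))
  names(p) <- sites$site
  p
}

#' Assign genetic propensities and ecological availabilities
#'
#' Independently for each behaviour, with probability `alpha_g` the genetic
#' propensity differs across sites: a point is drawn uniformly from the
#' sites' bounding box and the six propensities follow the distance gradient
#' of [gradient_probabilities()] (so the farthest site gets exactly 0).
#' Otherwise a single uniform(0, 1) draw is shared by all sites. Ecological
#' availabilities are assigned the same way, governed by `alpha_e`, but only
#' for food behaviours; social behaviours have availability fixed at 1.
#'
#' Uses the current RNG state; call `set.seed()` first for reproducibility.
#'
#' @param space Behaviour table from [behaviour_space()].
#' @param sites Site table from [site_map()].
#' @param alpha_g,alpha_e Probabilities in \[0, 1\] that a behaviour's
#'   genetic propensity / ecological availability differs across sites.
#' @return A tibble in long form with columns `behaviour_id`, `site`, `p_g`,
#'   `p_e` (one row per behaviour x site).
#' @examples
#' set.seed(1)
#' assign_propensities(behaviour_space(), site_map(), alpha_g = 0.2, alpha_e = 0.8)
#' @export
assign_propensities <- function(space, sites, alpha_g, alpha_e) {
  validate_site_map(sites)
  for (a in c(alpha_g, alpha_e)) {
    if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0 || a > 1) {
      rlang::abort("`alpha_g` and `alpha_e` must be single probabilities in [0, 1].",
        class = "exclusim_config_error"
      )
    }
  }
  n_beh <- nrow(space)
  n_site <- nrow(sites)
  is_food <- space$category == "food"
  box_x <- range(sites$x)
  box_y <- range(sites$y)

  draw_row <- function(alpha) {
    if (stats::runif(1) < alpha) {
      point <- c(stats::runif(1, box_x[1], box_x[2]), stats::runif(1, box_y[1], box_y[2]))
      unname(gradient_probabilities(point, sites))
    } else {
      rep(stats::runif(1), n_site)
    }
  }

  p_g <- matrix(NA_real_, n_beh, n_site)
  p_e <- matrix(1, n_beh, n_site)
  for (b in seq_len(n_beh)) {
    p_g[b, ] <- draw_row(alpha_g)
    if (is_food[b]) p_e[b, ] <- draw_row(alpha_e)
  }

  tibble::tibble(
    behaviour_id = rep(space$behaviour_id, each = n_site),
    site = rep(sites$site, times = n_beh),
    p_g = as.vector(t(p_g)),
    p_e = as.vector(t(p_e))
  )
}

# Long propensity tibble -> list of [behaviour x site] matrices, site order
# taken from `sites`.
propensity_matrices <- function(propensities, sites) {
  ids <- sort(unique(propensities$behaviour_id))
  site_idx <- match(propensities$site, sites$site)
  beh_idx <- match(propensities$behaviour_id, ids)
  p_g <- matrix(NA_real_, length(ids), nrow(sites),
    dimnames = list(ids, sites$site)
  )
  p_e <- p_g
  p_g[cbind(beh_idx, site_idx)] <- propensities$p_g
  p_e[cbind(beh_idx, site_idx)] <- propensities$p_e
  list(p_g = p_g, p_e = p_e)
}

#' Write a propensity table to CSV
#'
#' @param propensities Long table from [assign_propensities()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_propensities <- function(propensities, path) {
  readr::write_csv(propensities, path)
  invisible(path)
}

#' Read a world configuration file
#'
#' Reads a YAML (or JSON) configuration describing the world: an optional
#' `sites` list (name, x, y, n per site) and an optional `food_structure`
#' list (size, nutrient per sub-category). Missing parts fall back to the
#' package defaults.
#'
#' @param path Path to a YAML/JSON configuration file.
#' @return A list with elements `sites` (tibble) and `food_structure`
#'   (tibble), usable as `site_map`/`behaviour_space` inputs.
#' @export
read_world_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads bare y/n keys as booleans; map them back
  fix_keys <- function(rec) {
    nm <- names(rec)
    nm[nm == "TRUE"] <- "y"
    nm[nm == "FALSE"] <- "n"
    names(rec) <- nm
    rec
  }
  sites <- if (!is.null(cfg$sites)) {
    out <- dplyr::bind_rows(lapply(cfg$sites, function(r) tibble::as_tibble(fix_keys(r))))
    out$n <- as.integer(out$n)
    validate_site_map(out)
    out
  } else {
    site_map()
  }
  food <- if (!is.null(cfg$food_structure)) {
    dplyr::bind_rows(lapply(cfg$food_structure, function(r) {
      # YAML 1.1 reads a bare Y as boolean true
      if (is.logical(r$nutrient)) r$nutrient <- ifelse(r$nutrient, "Y", "N")
      tibble::as_tibble(r)
    }))
  } else {
    default_food_structure()
  }
  list(sites = sites, food_structure = food)
}
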