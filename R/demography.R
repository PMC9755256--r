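#' Initialize a population
#'
#' Creates `n` agents with ages drawn uniformly over whole months in
#' \[0, `init_max_age`) and empty behavioural repertoires. One simulation
#' step is one month of life.
#'
#' @param n Number of agents (fixed for the population's lifetime).
#' @param n_behaviours Number of latent behaviours (64 by default).
#' @param init_max_age Exclusive upper bound, in months, for initial ages
#'   (default 300 months = 25 years).
#' @param site Optional site label carried along for bookkeeping.
#' @return A population object: a list with integer vector `age`, logical
#'   repertoire matrix `rep` (agents x behaviours) and `site`.
#' @examples
#' set.seed(1)
#' pop <- init_population(20)
#' range(pop$age)
#' @export
init_population <- function(n, n_behaviours = 64L, init_max_age = 300L, site = NA_character_) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    rlang::abort("`n` must be a single integer >= 1.", class = "exclusim_config_error")
  }
  n <- as.integer(n)
  structure(
    list(
      site = site,
      age = sample.int(as.integer(init_max_age), n, replace = TRUE) - 1L,
      rep = matrix(FALSE, nrow = n, ncol = as.integer(n_behaviours))
    ),
    class = "culture_pop"
  )
}

#' @export
print.culture_pop <- function(x, ...) {
  cat(
    "<culture_pop> ", nrow(x$rep), " agents",
    if (!is.na(x$site)) paste0(" at ", x$site), "\n",
    "  ages (months): ", min(x$age), "-", max(x$age),
    "; mean repertoire size: ", round(mean(rowSums(x$rep)), 2), "\n",
    sep = ""
  )
  invisible(x)
}

#' Advance a population by one month of births and deaths
#'
#' Every agent's age increases by one month. Agents whose (incremented) age
#' is at least `death_onset` die with probability `death_hazard` that month;
#' any agent exceeding `max_age` dies with certainty. Each dead agent is
#' replaced in place by a newborn (age 0, empty repertoire), so the
#' population size never changes.
#'
#' @param pop A population from [init_population()].
#' @param death_onset Age in months at which the monthly death hazard starts
#'   (default 300 = 25 years).
#' @param death_hazard Monthly death probability from `death_onset` on
#'   (default 0.01).
#' @param max_age Maximum age in months; exceeding it is lethal
#'   (default 720 = 60 years).
#' @return The updated population.
#' @export
demographic_step <- function(pop, death_onset = 300L, death_hazard = 0.01, max_age = 720L) {
  age <- pop$age + 1L
  dead <- (age >= death_onset & runif(length(age)) < death_hazard) | age > max_age
  if (any(dead)) {
    age[dead] <- 0L
    pop$rep[dead, ] <- FALSE
  }
  pop$age <- age
  pop
}
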