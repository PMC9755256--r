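LEVELS <- c("customary", "habitual", "present", "absent", "ecological_explanation")
EXPRESSED_LEVELS <- c("customary", "habitual", "present")

#' Classify one behaviour in one population
#'
#' Method-of-exclusion frequency levels: *customary* if strictly more than
#' 50% of the members of at least one (non-empty) age class express the
#' behaviour; otherwise *habitual* with at least two expressers in the
#' population, *present* with exactly one, and with none either
#' *ecological_explanation* (when local ecological availability is exactly
#' 0, so the behaviour could never be expressed there) or plain *absent*.
#'
#' @param expressed Logical vector, one entry per agent.
#' @param ages Integer agent ages in months.
#' @param p_e Local ecological availability of the behaviour (default 1).
#' @param age_breaks Month cut-points defining age classes (default 192 and
#'   480).
#' @return A single level string.
#' @examples
#' classify_behaviour(rep(c(TRUE, FALSE), c(5, 3)), rep(100, 8)) # customary
#' @export
classify_behaviour <- function(expressed, ages, p_e = 1, age_breaks = c(192L, 480L)) {
  cls <- findInterval(ages, age_breaks) + 1L
  sizes <- tabulate(cls, nbins = length(age_breaks) + 1L)
  expr_by_cls <- tabulate(cls[expressed], nbins = length(age_breaks) + 1L)
  customary <- any(sizes > 0 & expr_by_cls > 0.5 * sizes)
  total <- sum(expressed)
  if (customary) {
    "customary"
  } else if (total >= 2) {
    "habitual"
  } else if (total == 1) {
    "present"
  } else if (p_e == 0) {
    "ecological_explanation"
  } else {
    "absent"
  }
}

# Census over final populations; p_e is a [behaviour x site] matrix aligned
# with `space` rows and `sites` rows.
census_from_populations <- function(pops, sites, space, p_e, age_breaks) {
  out <- vector("list", length(pops))
  k <- length(age_breaks) + 1L
  for (j in seq_along(pops)) {
    pop <- pops[[j]]
    cls <- findInterval(pop$age, age_breaks) + 1L
    sizes <- tabulate(cls, nbins = k)
    cnt_cls <- rowsum(pop$rep + 0, cls)
    present_cls <- as.integer(rownames(cnt_cls))
    customary <- colSums(cnt_cls > 0.5 * sizes[present_cls]) > 0
    total <- colSums(pop$rep)
    level <- ifelse(customary, "customary",
      ifelse(total >= 2, "habitual",
        ifelse(total == 1, "present",
          ifelse(p_e[, j] == 0, "ecological_explanation", "absent")
        )
      )
    )
    out[[j]] <- tibble::tibble(
      behaviour_id = space$behaviour_id, site = sites$site[j],
      level = level
    )
  }
  census <- dplyr::bind_rows(out)
  census$level <- factor(census$level, levels = LEVELS)
  dplyr::arrange(census, .data$behaviour_id, match(.data$site, sites$site))
}

#' Census table of a finished simulation
#'
#' Recomputes the behaviour x site classification from the simulation's
#' final populations, optionally with different age-class boundaries.
#'
#' @param sim A `culture_sim` from [run_simulation()].
#' @param age_breaks Month cut-points defining age classes; defaults to the
#'   run's own setting.
#' @return A tibble with columns `behaviour_id`, `site`, `level`.
#' @export
census_table <- function(sim, age_breaks = sim$params$age_breaks) {
  mats <- propensity_matrices(sim$propensities, sim$sites)
  ord <- match(sim$space$behaviour_id, as.integer(rownames(mats$p_e)))
  census_from_populations(
    sim$populations, sim$sites, sim$space,
    mats$p_e[ord, , drop = FALSE], age_breaks
  )
}

#' Assign distribution patterns A-D
#'
#' Evaluated in precedence order:
#' * **A** — absent at no site (expressed everywhere);
#' * **B** — not reaching habitual frequencies at any site;
#' * **C** — every absence explained by local ecological factors;
#' * **D** — customary or habitual somewhere yet absent elsewhere with no
#'   ecological explanation: the "cultural" pattern of the method of
#'   exclusion.
#'
#' The order makes the four patterns exhaustive and mutually exclusive.
#'
#' @param census Census table from [census_table()].
#' @return A tibble with columns `behaviour_id` and `pattern` (factor
#'   A/B/C/D).
#' @export
assign_patterns <- function(census) {
  summ <- census |>
    dplyr::group_by(.data$behaviour_id) |>
    dplyr::summarise(
      any_unexpressed = any(!.data$level %in% EXPRESSED_LEVELS),
      any_habitual_plus = any(.data$level %in% c("customary", "habitual")),
      any_plain_absent = any(.data$level == "absent"),
      .groups = "drop"
    )
  pattern <- dplyr::case_when(
    !summ$any_unexpressed ~ "A",
    !summ$any_habitual_plus ~ "B",
    !summ$any_plain_absent ~ "C",
    TRUE ~ "D"
  )
  tibble::tibble(
    behaviour_id = summ$behaviour_id,
    pattern = factor(pattern, levels = c("A", "B", "C", "D"))
  )
}

#' Count cultural (pattern-D) behaviours
#'
#' @param patterns A pattern table from [assign_patterns()] or a
#'   `culture_sim` object.
#' @return Integer count of pattern-D behaviours.
#' @export
count_cultural <- function(patterns) {
  if (inherits(patterns, "culture_sim")) patterns <- patterns$patterns
  sum(patterns$pattern == "D")
}

#' Locally restricted behaviours
#'
#' Behaviours expressed (present, habitual or customary) at exactly one
#' site — the focus of the method of local restriction.
#'
#' @param census Census table from [census_table()].
#' @return Integer vector of behaviour ids.
#' @export
locally_restricted <- function(census) {
  if (inherits(census, "culture_sim")) census <- census$census
  tab <- census |>
    dplyr::group_by(.data$behaviour_id) |>
    dplyr::summarise(n_sites = sum(.data$level %in% EXPRESSED_LEVELS), .groups = "drop")
  tab$behaviour_id[tab$n_sites == 1L]
}

#' Per-population counts of expressed cultural behaviours
#'
#' For each site, how many pattern-D behaviours are expressed there
#' (present, habitual or customary). These counts, paired with population
#' sizes, feed the size-versus-culture correlation.
#'
#' @param census Census table from [census_table()].
#' @param patterns Matching pattern table from [assign_patterns()].
#' @return A tibble with columns `site` and `n_cultural`.
#' @export
per_population_cultural_counts <- function(census, patterns) {
  d_ids <- patterns$behaviour_id[patterns$pattern == "D"]
  census |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(
      n_cultural = sum(.data$behaviour_id %in% d_ids &
        .data$level %in% EXPRESSED_LEVELS),
      .groups = "drop"
    )
}

#' Write a census grid to TSV
#'
#' Behaviours as rows, sites as columns, cells coded C (customary),
#' H (habitual), P (present), `-` (absent) and E (absent with ecological
#' explanation) — a text analogue of the classic site-by-behaviour figure.
#'
#' @param census Census table from [census_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_census <- function(census, path) {
  codes <- c(
    customary = "C", habitual = "H", present = "P",
    absent = "-", ecological_explanation = "E"
  )
  wide <- census |>
    dplyr::mutate(code = codes[as.character(.data$level)]) |>
    dplyr::select("behaviour_id", "site", "code") |>
    tidyr::pivot_wider(names_from = "site", values_from = "code")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Write a pattern table to CSV
#'
#' Writes `behaviour_id,pattern` rows preceded by a `#` summary line with
#' the A/B/C/D totals (readable back with `comment = "#"`).
#'
#' @param patterns Pattern table from [assign_patterns()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_patterns <- function(patterns, path) {
  counts <- table(patterns$pattern)
  writeLines(sprintf(
    "# A=%d B=%d C=%d D=%d",
    counts["A"], counts["B"], counts["C"], counts["D"]
  ), path)
  readr::write_csv(patterns, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
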