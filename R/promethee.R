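# PROMETHEE-style outranking comparison of scenarios. For each criterion
# (one combination of sustainability measure, habitat-loss class, species
# and starting condition) every scenario pair is compared; the scenario
# that maximises the criterion gains a point only when the difference is
# significant (two-sided Mann-Whitney U test, P < 0.05), with the direction
# taken from the sample means. Deterministic scalar criteria (city green
# space) use strict inequality. Partial matrices sum to a total preference
# matrix; scenarios are ranked both by total wins (row sums, descending)
# and by total losses (column sums, ascending), and the solution is robust
# when the two orders agree, ties included. All criteria carry equal weight.

#' Partial preference matrix for one criterion
#'
#' @param samples Named list (one element per scenario) of numeric
#'   replicate-value vectors, or a named numeric vector of scalars for a
#'   deterministic criterion.
#' @param alpha_level Significance gate for the Mann-Whitney test (default
#'   0.05). Small untied samples are tested exactly; otherwise the normal
#'   approximation with tie correction is used (the `stats::wilcox.test`
#'   convention).
#' @return A square 0/1 matrix `pi` with `pi[a, b] = 1` when scenario `a` is
#'   preferred to `b`; `pi[a, b] + pi[b, a] <= 1` and the diagonal is 0.
#' @export
partial_preference <- function(samples, alpha_level = 0.05) {
  scalar <- is.numeric(samples) && !is.list(samples)
  nms <- names(samples)
  if (is.null(nms) || anyDuplicated(nms))
    abort("samples must be uniquely named by scenario")
  k <- length(samples)
  pi_m <- matrix(0L, k, k, dimnames = list(nms, nms))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      if (scalar) {
        va <- samples[[a]]; vb <- samples[[b]]
        if (va > vb) pi_m[a, b] <- 1L
        if (vb > va) pi_m[b, a] <- 1L
      } else {
        xa <- samples[[a]]; xb <- samples[[b]]
        if (length(unique(c(xa, xb))) == 1) next
        pv <- suppressWarnings(
          wilcox.test(xa, xb, alternative = "two.sided")$p.value)
        if (is.na(pv) || pv >= alpha_level) next
        ma <- mean(xa); mb <- mean(xb)
        if (ma > mb) pi_m[a, b] <- 1L
        if (mb > ma) pi_m[b, a] <- 1L
      }
    }
  }
  pi_m
}

#' Total preference matrix
#'
#' Element-wise sum of partial preference matrices over all criteria.
#'
#' @param partials A list of matrices from [partial_preference()], all with
#'   the same scenario set.
#' @return An integer matrix; entry (a, b) counts the criteria on which `a`
#'   was significantly preferred to `b`, bounded by the criterion count.
#' @export
total_preference <- function(partials) {
  stopifnot(length(partials) >= 1)
  nms <- dimnames(partials[[1]])[[1]]
  for (p in partials) {
    if (!identical(dimnames(p)[[1]], nms))
      abort("partial preference matrices have mismatched scenario sets")
  }
  Reduce(`+`, partials)
}

#' Rank scenarios from a total preference matrix
#'
#' Wins ranking: descending row sums (times a scenario won). Losses
#' ranking: ascending column sums (times it lost). The solution is robust
#' when both orders are identical, tie structure included; differing orders
#' mean some scenarios are incomparable on the available information.
#'
#' @param total Matrix from [total_preference()].
#' @return An object of class `promethee_ranking`: a list with `table` (a
#'   tibble: `scenario`, `wins`, `losses`, `wins_rank`, `losses_rank`) and
#'   `robust` (logical).
#' @export
rank_scenarios <- function(total) {
  wins <- rowSums(total)
  losses <- colSums(total)
  wins_rank <- rank(-wins, ties.method = "min")
  losses_rank <- rank(losses, ties.method = "min")
  tab <- tibble::tibble(scenario = rownames(total), wins = as.integer(wins),
                        losses = as.integer(losses),
                        wins_rank = as.integer(wins_rank),
                        losses_rank = as.integer(losses_rank))
  tab <- dplyr::arrange(tab, .data$wins_rank, .data$scenario)
  structure(list(table = tab, robust = all(wins_rank == losses_rank)),
            class = "promethee_ranking")
}

#' @export
print.promethee_ranking <- function(x, ...) {
  cat(sprintf("<promethee_ranking> robust: %s\n", x$robust))
  print(x$table)
  invisible(x)
}

#' @rdname rank_scenarios
#' @param x A `promethee_ranking`.
#' @param ... Unused.
#' @export
tidy.promethee_ranking <- function(x, ...) x$table

#' @rdname rank_scenarios
#' @export
glance.promethee_ranking <- function(x, ...) {
  tibble::tibble(robust = x$robust,
                 n_scenarios = nrow(x$table),
                 total_points = sum(x$table$wins),
                 top_by_wins = x$table$scenario[x$table$wins_rank == 1][1])
}

#' Enumerate the criteria of a factorial design
#'
#' One criterion per combination of sustainability measure, habitat-loss
#' class, species and starting condition. With the full design of 5
#' measures, 9 loss classes, 10 species and 200 starting conditions this
#' yields 90,000 criteria. The green-space measure, although constant
#' across starting conditions and replicates, is enumerated like the
#' others so each combination carries equal weight.
#'
#' @param measures Character vector of measure names.
#' @param levels Numeric vector of habitat-loss percentages.
#' @param species Character vector of species.
#' @param starting_conditions Integer vector (or count) of starting
#'   condition ids.
#' @return A tibble with one row per criterion: `measure`, `level`,
#'   `species`, `starting_condition`.
#' @export
enumerate_criteria <- function(measures, levels, species, starting_conditions) {
  if (length(starting_conditions) == 1 && is.numeric(starting_conditions))
    starting_conditions <- seq_len(starting_conditions)
  tidyr::expand_grid(measure = measures, level = levels, species = species,
                     starting_condition = starting_conditions)
}

#' PROMETHEE analysis of a measures table
#'
#' Builds one criterion per (measure, level, species, starting condition)
#' cell of a per-replicate measures table, computes the Mann-Whitney-gated
#' partial preference matrix for each, sums them and ranks the scenarios.
#' The factorial must be complete: every cell must hold a sample for every
#' scenario.
#'
#' @param measures_tbl Long tibble with columns `species`, `scenario`,
#'   `level`, `starting_condition`, `replicate`, one column per vector
#'   measure (`min_occupancy_pct`, `occupancy_pct_t175`, `survival`,
#'   `city_survival`) and the scalar `city_green_space_ha`.
#' @param measure_names Vector measures to use (default the four replicate
#'   measures).
#' @param scalar_measures Scalar measures to use (default city green
#'   space).
#' @param alpha_level Mann-Whitney significance gate.
#' @param grouping `"none"` for one overall ranking, or the name of a
#'   column in `measures_tbl` (e.g. a species-group column) or `"measure"`
#'   to rank within groups.
#' @return For `grouping = "none"` a list with `total` (matrix), `ranking`
#'   (a `promethee_ranking`) and `n_criteria`; otherwise a tibble of
#'   per-group rankings with list-columns `total` and `ranking`.
#' @export
promethee_analysis <- function(measures_tbl,
                               measure_names = c("min_occupancy_pct",
                                                 "occupancy_pct_t175",
                                                 "survival", "city_survival"),
                               scalar_measures = "city_green_space_ha",
                               alpha_level = 0.05,
                               grouping = "none") {
  scen <- sort(unique(measures_tbl$scenario))
  cells <- dplyr::distinct(measures_tbl, .data$species, .data$level,
                           .data$starting_condition)
  got <- dplyr::count(measures_tbl, .data$species, .data$level,
                      .data$starting_condition, .data$scenario)
  chk <- dplyr::count(got, .data$species, .data$level,
                      .data$starting_condition, name = "n_scen")
  bad <- chk[chk$n_scen != length(scen), , drop = FALSE]
  if (nrow(bad) > 0)
    abort(paste0("incomplete factorial: ", nrow(bad),
                 " cell(s) lack some scenario, e.g. species=", bad$species[1],
                 " level=", bad$level[1], " sc=", bad$starting_condition[1]))

  one_cell <- function(sp, lv, sc) {
    sub <- measures_tbl[measures_tbl$species == sp & measures_tbl$level == lv &
                          measures_tbl$starting_condition == sc, , drop = FALSE]
    parts <- list()
    for (m in measure_names) {
      samples <- lapply(setNames(scen, scen),
                        function(s) sub[[m]][sub$scenario == s])
      parts[[m]] <- partial_preference(samples, alpha_level)
    }
    for (m in scalar_measures) {
      vals <- vapply(setNames(scen, scen),
                     function(s) sub[[m]][sub$scenario == s][1], numeric(1))
      parts[[m]] <- partial_preference(vals, alpha_level)
    }
    parts
  }

  all_parts <- purrr::pmap(list(cells$species, cells$level,
                                cells$starting_condition), one_cell)

  summarise_group <- function(part_sets, keep_measures) {
    mats <- unlist(lapply(part_sets, function(ps) ps[keep_measures]),
                   recursive = FALSE)
    total <- total_preference(mats)
    list(total = total, ranking = rank_scenarios(total),
         n_criteria = length(mats))
  }

  all_measures <- c(measure_names, scalar_measures)
  if (identical(grouping, "none")) {
    return(summarise_group(all_parts, all_measures))
  }
  if (identical(grouping, "measure")) {
    res <- purrr::map(setNames(all_measures, all_measures),
                      function(m) summarise_group(all_parts, m))
  } else {
    key <- measures_tbl[[grouping]]
    if (is.null(key)) abort(paste0("unknown grouping column: ", grouping))
    cell_key <- dplyr::distinct(measures_tbl, .data$species,
                                g = .data[[grouping]])
    gmap <- setNames(cell_key$g, cell_key$species)
    groups <- unique(gmap)
    res <- purrr::map(setNames(groups, groups), function(g) {
      idx <- which(gmap[cells$species] == g)
      summarise_group(all_parts[idx], all_measures)
    })
  }
  tibble::tibble(group = names(res),
                 n_criteria = vapply(res, function(r) r$n_criteria, numeric(1)),
                 total = lapply(res, function(r) r$total),
                 ranking = lapply(res, function(r) r$ranking))
}
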