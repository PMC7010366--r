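# Classic incidence function model (IFM), the stochastic patch-occupancy
# model of Hanski. For patch i with area A_i (ha) at centroid distance d_ij
# (km) from patch j:
#   connectivity   S_i = sum_{j != i} p_j * exp(-alpha * d_ij) * A_j^b
#   colonisation   C_i = S_i^2 / (S_i^2 + y^2)
#   extinction     E_i = min(1, (e * y^2 / y^2) / A_i^x)
#   rescue effect  effective extinction = E_i * (1 - C_i)
# e and y are not separately identifiable from incidence data, so y is fixed
# at 1 and the compound e*y^2 ("ey2") is the extinction scalar. Updates are
# synchronous, with connectivity computed from the previous state; the
# all-empty state is absorbing.

#' IFM parameter set
#'
#' @param alpha Dispersal-decay rate, km^-1. With an exponential dispersal
#'   kernel, `alpha = 1 / mean_dispersal_km`.
#' @param x Extinction-area exponent.
#' @param ey2 Combined extinction scalar e*y^2 (units ha^x).
#' @param b Connectivity area exponent (classic default 1).
#' @param y Colonisation half-saturation (fixed 1 by identifiability
#'   convention).
#' @param rescue Apply the rescue effect (default `TRUE`).
#' @param fitted_coefs Optional named vector `(intercept, coef_lnA,
#'   coef_lnS)` recorded by [fit_ifm()].
#' @return A list of class `ifm_params`.
#' @export
ifm_params <- function(alpha, x, ey2, b = 1, y = 1, rescue = TRUE,
                       fitted_coefs = NULL) {
  p <- structure(list(alpha = alpha, x = x, ey2 = ey2, b = b, y = y,
                      rescue = rescue, fitted_coefs = fitted_coefs),
                 class = "ifm_params")
  validate_ifm_params(p)
  p
}

#' @noRd
validate_ifm_params <- function(p) {
  stopifnot(inherits(p, "ifm_params"))
  if (!is.finite(p$alpha) || p$alpha <= 0) abort("alpha must be > 0")
  if (!is.finite(p$x)) abort("x must be finite")
  if (!is.finite(p$ey2) || p$ey2 < 0) abort("ey2 must be >= 0")
  if (!is.finite(p$y) || p$y <= 0) abort("y must be > 0")
  invisible(p)
}

#' @export
print.ifm_params <- function(x, ...) {
  cat(sprintf("<ifm_params> alpha=%.4g km^-1, x=%.4g, e*y^2=%.4g, b=%g, y=%g, rescue=%s\n",
              x$alpha, x$x, x$ey2, x$b, x$y, x$rescue))
  invisible(x)
}

# connectivity kernel matrix K_ij = exp(-alpha * d_ij) * A_j^b, diag 0;
# S = K %*% p
#' @noRd
ifm_kernel <- function(patches, alpha, b = 1) {
  n <- nrow(patches)
  d_km <- as.matrix(stats::dist(cbind(patches$cx, patches$cy))) / 1000
  K <- exp(-alpha * d_km) * matrix(patches$area_ha^b, n, n, byrow = TRUE)
  diag(K) <- 0
  K
}

#' Connectivity of every patch given an occupancy state
#'
#' `S_i = sum_{j != i} p_j * exp(-alpha * d_ij) * A_j^b` with centroid
#' distances in km and areas in ha.
#'
#' @param patches Patch tibble (`area_ha`, `cx`, `cy`).
#' @param state Binary occupancy vector, one element per patch row.
#' @param alpha Dispersal-decay rate, km^-1.
#' @param b Connectivity area exponent.
#' @return Numeric vector of connectivities.
#' @export
ifm_connectivity <- function(patches, state, alpha, b = 1) {
  stopifnot(alpha > 0, length(state) == nrow(patches))
  if (nrow(patches) == 0) return(numeric(0))
  as.numeric(ifm_kernel(patches, alpha, b) %*% as.numeric(state))
}

#' Colonisation and extinction probabilities
#'
#' @param area_ha Patch area(s), ha.
#' @param S Connectivity value(s).
#' @param params An [ifm_params()].
#' @return A tibble with columns `C` (colonisation), `E` (extinction) and
#'   `E_eff` (effective extinction after the rescue effect, if enabled).
#' @export
ifm_transition_probs <- function(area_ha, S, params) {
  validate_ifm_params(params)
  if (any(area_ha <= 0)) abort("patch areas must be > 0")
  C <- S^2 / (S^2 + params$y^2)
  C[S == 0] <- 0
  E <- pmin(1, (params$ey2 / params$y^2) / area_ha^params$x)
  E_eff <- if (params$rescue) E * (1 - C) else E
  tibble::tibble(C = C, E = E, E_eff = E_eff)
}

# one synchronous transition given precomputed kernel K and extinction
# vector E (constant across steps); inlined for hot loops
#' @noRd
ifm_step_kernel <- function(state, K, area_ha, params,
                            E = pmin(1, (params$ey2 / params$y^2) /
                                       area_ha^params$x)) {
  S <- as.numeric(K %*% state)
  C <- S * S / (S * S + params$y^2)
  E_eff <- if (params$rescue) E * (1 - C) else E
  r <- runif(length(state))
  as.integer(ifelse(state == 1L, r < 1 - E_eff, r < C))
}

#' One synchronous IFM transition
#'
#' Occupied patches survive with probability `1 - E_i * (1 - C_i)`; empty
#' patches are colonised with probability `C_i`. Connectivity is computed
#' from the supplied (previous) state.
#'
#' @param state Binary occupancy vector.
#' @param patches Patch tibble.
#' @param params An [ifm_params()].
#' @return The next binary occupancy vector.
#' @export
ifm_step <- function(state, patches, params) {
  validate_ifm_params(params)
  K <- ifm_kernel(patches, params$alpha, params$b)
  ifm_step_kernel(as.integer(state), K, patches$area_ha, params)
}

#' Simulate the IFM
#'
#' Runs `reps` independent replicate chains of [ifm_step()] for `steps`
#' transitions from a common starting condition. The all-empty state is
#' absorbing: once a replicate goes globally extinct its remaining
#' timesteps are stored as zeros without further simulation.
#'
#' @param initial Binary starting occupancy (vector, or tibble with
#'   `patch_id` and `occupied` matching `patches`).
#' @param patches Patch tibble.
#' @param params An [ifm_params()].
#' @param steps Number of transitions (default 500).
#' @param reps Number of replicates (default 100).
#' @param seed Integer seed; replicate r runs under a child seed derived
#'   from it, recorded in the result.
#' @return An object of class `ifm_trajectories`: list with `occ` (integer
#'   array `reps x (steps + 1) x n_patches`; timestep 0 is the starting
#'   condition), `patch_id`, `area_ha`, `params`, `seeds`.
#' @export
ifm_simulate <- function(initial, patches, params, steps = 500, reps = 100,
                         seed = 1L) {
  validate_ifm_params(params)
  stopifnot(steps >= 1, reps >= 1)
  n <- nrow(patches)
  if (is.data.frame(initial))
    initial <- initial$occupied[match(patches$patch_id, initial$patch_id)]
  initial <- as.integer(initial)
  if (n == 0) {
    occ <- array(0L, dim = c(reps, steps + 1, 0))
    return(structure(list(occ = occ, patch_id = integer(0),
                          area_ha = numeric(0), params = params,
                          seeds = child_seed(seed, seq_len(reps)),
                          zero_habitat = TRUE),
                     class = "ifm_trajectories"))
  }
  stopifnot(length(initial) == n, all(initial %in% c(0L, 1L)))
  K <- ifm_kernel(patches, params$alpha, params$b)
  E <- pmin(1, (params$ey2 / params$y^2) / patches$area_ha^params$x)
  occ <- array(0L, dim = c(reps, steps + 1, n))
  seeds <- vapply(seq_len(reps), function(r) child_seed(seed, r), integer(1))
  for (r in seq_len(reps)) {
    with_seed(seeds[r], {
      state <- initial
      occ[r, 1, ] <- state
      for (t in seq_len(steps)) {
        if (all(state == 0L)) break # absorbing; zeros already stored
        state <- ifm_step_kernel(state, K, patches$area_ha, params, E)
        occ[r, t + 1, ] <- state
      }
    })
  }
  structure(list(occ = occ, patch_id = patches$patch_id,
                 area_ha = patches$area_ha, params = params, seeds = seeds,
                 zero_habitat = FALSE),
            class = "ifm_trajectories")
}

#' @export
print.ifm_trajectories <- function(x, ...) {
  d <- dim(x$occ)
  cat(sprintf("<ifm_trajectories> %d replicates x %d timesteps x %d patches\n",
              d[1], d[2] - 1, d[3]))
  invisible(x)
}

#' Fit IFM parameters to a multi-year occupancy history
#'
#' Pools (patch, year) observations and fits a Bernoulli logistic regression
#' of occupancy on `ln A_i` and `ln S_i(t)`, with connectivity computed from
#' the same year's occupancy of the other patches. The incidence identity
#' `logit J_i = -ln(e*y^2) + 2 ln S_i + x ln A_i` maps coefficients to
#' simulation parameters: `x` is the `ln A` coefficient and
#' `ey2 = exp(-intercept)` with `y` fixed at 1. In `"constrained"` mode
#' `ln S` enters as an offset with its theoretical coefficient 2; the
#' default `"unconstrained"` mode estimates it freely (a value near 2 is a
#' model-adequacy check). Observations with `S = 0` are dropped (their
#' count is recorded).
#'
#' @param history Year-by-patch binary matrix (rows = years), as from
#'   [generate_occupancy_history()].
#' @param patches Patch tibble matching the history's columns.
#' @param alpha Dispersal-decay rate used for connectivity, km^-1.
#' @param mode `"unconstrained"` (default) or `"constrained"`.
#' @param b Connectivity area exponent.
#' @param species Optional species name used in error messages.
#' @return An object of class `ifm_fit`: list with `params` (an
#'   [ifm_params()] carrying `fitted_coefs`), `fit` (the `glm`), `mode`,
#'   `n_obs`, `n_dropped`.
#' @export
fit_ifm <- function(history, patches, alpha, mode = c("unconstrained",
                                                      "constrained"),
                    b = 1, species = NULL) {
  mode <- match.arg(mode)
  if (!is.matrix(history) || nrow(history) < 2)
    abort("history must be a matrix with >= 2 years")
  n <- nrow(patches)
  stopifnot(ncol(history) == n)
  who <- if (is.null(species)) "" else paste0(" for ", species)
  K <- ifm_kernel(patches, alpha, b)
  obs <- purrr::map_dfr(seq_len(nrow(history)), function(t) {
    S <- as.numeric(K %*% history[t, ])
    tibble::tibble(occ = history[t, ], lnA = log(patches$area_ha), S = S)
  })
  n_dropped <- sum(obs$S == 0)
  obs <- obs[obs$S > 0, , drop = FALSE]
  obs$lnS <- log(obs$S)
  if (nrow(obs) < 10)
    abort(paste0("fewer than 10 usable observations", who))
  if (length(unique(obs$occ)) < 2)
    abort(paste0("no variation in occupancy (complete separation)", who))
  fit <- withCallingHandlers(
    if (mode == "constrained")
      glm(occ ~ lnA + offset(2 * lnS), family = binomial(), data = obs)
    else
      glm(occ ~ lnA + lnS, family = binomial(), data = obs),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        abort(paste0("complete separation in IFM fit", who))
      invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    abort(paste0("IFM logistic regression did not converge", who))
  cf <- coef(fit)
  coefs <- c(intercept = unname(cf[1]), coef_lnA = unname(cf["lnA"]),
             coef_lnS = if (mode == "constrained") 2 else unname(cf["lnS"]))
  params <- ifm_params(alpha = alpha, x = unname(cf["lnA"]),
                       ey2 = exp(-unname(cf[1])), b = b, y = 1,
                       fitted_coefs = coefs)
  structure(list(params = params, fit = fit, mode = mode,
                 n_obs = nrow(obs), n_dropped = n_dropped, species = species),
            class = "ifm_fit")
}

#' @export
print.ifm_fit <- function(x, ...) {
  cat(sprintf("<ifm_fit> %s: x=%.3f, e*y^2=%.4f (%d obs, %d dropped with S=0)\n",
              x$mode, x$params$x, x$params$ey2, x$n_obs, x$n_dropped))
  invisible(x)
}

#' @rdname fit_ifm
#' @param x An `ifm_fit` object.
#' @param ... Unused.
#' @export
tidy.ifm_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @rdname fit_ifm
#' @export
glance.ifm_fit <- function(x, ...) {
  obj <- x
  tibble::tibble(x = obj$params$x, ey2 = obj$params$ey2,
                 alpha = obj$params$alpha,
                 coef_lnS = unname(obj$params$fitted_coefs["coef_lnS"]),
                 mode = obj$mode, n_obs = obj$n_obs, n_dropped = obj$n_dropped,
                 deviance = obj$fit$deviance, aic = obj$fit$aic)
}
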