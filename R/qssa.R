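# Gillespie SSA, occupancy estimation, QSSA propensity averaging over
# analytic fast-subsystem equilibria, and the slow-scale SSA.

#' Simulate a reaction network with the (direct-method) Gillespie SSA
#'
#' Exact-in-law realization of the Markov jump process: at each state,
#' independent exponential waiting times with the channel propensities; the
#' shortest specifies the reaction that fires. Mass-action networks run in
#' compiled code; networks with explicit propensity rules fall back to an R
#' loop. Reproducible: the realization is a deterministic function of
#' `seed` (R's RNG is seeded with it).
#'
#' @param network an `eq_network`.
#' @param X0 initial state.
#' @param t_end simulation horizon.
#' @param seed integer seed.
#' @param max_steps step-count guard (error if exceeded).
#' @return object of class `"eq_trajectory"`: `times` (including 0),
#'   `states` (matrix, one row per time point), `t_end`.
#' @export
ssa_simulate <- function(network, X0, t_end, seed, max_steps = 5e6) {
  X0 <- as.integer(round(X0))
  stopifnot(t_end > 0)
  set.seed(seed)
  custom <- any(vapply(network$reactions, function(r) !is.null(r$propensity),
                       logical(1)))
  if (!custom) {
    n <- length(network$species)
    alpha <- matrix(vapply(network$reactions, `[[`, integer(n), "reactant"),
                    nrow = n)
    res <- ssa_core(alpha, network$nu,
                    vapply(network$reactions, `[[`, numeric(1), "rate"),
                    X0, t_end, as.integer(max_steps))
    if (length(res$times) >= max_steps)
      stop("step-limit error: SSA exceeded max_steps before t_end")
    if (length(res$rxn) == 0L) {
      states <- matrix(X0, nrow = 1)
    } else {
      dX <- network$nu[, res$rxn, drop = FALSE]        # n x steps
      cum <- matrix(t(apply(dX, 1, cumsum)), nrow = n) # n x steps
      states <- rbind(X0, t(cum + X0))
    }
  } else {
    times <- numeric(0); rxns <- integer(0)
    t <- 0; X <- X0
    Xs <- list(X0)
    repeat {
      a <- propensities(network, X)
      a0 <- sum(a)
      if (a0 <= 0) break
      tau <- rexp(1, a0)
      if (t + tau > t_end) break
      t <- t + tau
      h <- sample.int(length(a), 1, prob = a)
      X <- X + network$nu[, h]
      times <- c(times, t); Xs[[length(Xs) + 1L]] <- X
      if (length(times) > max_steps)
        stop("step-limit error: SSA exceeded max_steps before t_end")
    }
    res <- list(times = times)
    states <- do.call(rbind, Xs)
  }
  colnames(states) <- network$species
  structure(list(times = c(0, res$times), states = states, t_end = t_end,
                 species = network$species, seed = seed),
            class = "eq_trajectory")
}

#' @export
print.eq_trajectory <- function(x, ...) {
  cat(sprintf("SSA trajectory: %d jumps on [0, %g], %d species\n",
              length(x$times) - 1L, x$t_end, ncol(x$states)))
  invisible(x)
}

#' Occupation-time-weighted empirical distribution of a trajectory
#'
#' Time-weighted occupancy of the visited states after `burn_in`. When
#' `space` is supplied the result is expressed on that enumeration (states
#' never visited get probability zero), directly comparable with analytic
#' equilibria.
#'
#' @param traj an `eq_trajectory`.
#' @param burn_in initial time span to discard (`< t_end`).
#' @param space optional `eq_space` fixing the support and ordering.
#' @return an `eq_distribution`.
#' @export
empirical_distribution <- function(traj, burn_in = 0, space = NULL) {
  stopifnot(traj$t_end > burn_in)
  times <- c(traj$times, traj$t_end)
  dur <- pmax(pmin(times[-1], traj$t_end) - pmax(times[-length(times)], burn_in), 0)
  keys <- apply(traj$states, 1, paste, collapse = ",")
  occ <- tapply(dur, keys, sum)
  if (is.null(space)) {
    probs <- as.numeric(occ) / sum(occ)
    # deterministic order: first-visit order of states
    first <- !duplicated(keys)
    ord_keys <- keys[first]
    probs <- as.numeric(occ[ord_keys]) / sum(occ)
    S <- traj$states[first, , drop = FALSE]
    return(equilibrium_distribution(probs, new_space(S)))
  }
  probs <- numeric(n_states(space))
  skeys <- apply(space$states, 1, paste, collapse = ",")
  m <- match(names(occ), skeys)
  if (any(is.na(m))) stop("trajectory visited states outside the given space")
  probs[m] <- as.numeric(occ)
  equilibrium_distribution(probs / sum(probs), space)
}

#' QSSA-averaged propensity
#'
#' Law of total expectation: the effective slow-scale propensity is the
#' inner product of the fast-subsystem equilibrium with the per-fast-state
#' slow propensities, e.g. the effective mRNA expression rate
#' a_u Pr_QSS(free) + a_b Pr_QSS(bound).
#'
#' @param fast_eq an `eq_distribution` (or probability vector) over fast states.
#' @param slow_propensity_per_fast_state numeric vector, same length.
#' @return averaged propensity (scalar).
#' @export
averaged_propensity <- function(fast_eq, slow_propensity_per_fast_state) {
  p <- if (inherits(fast_eq, "eq_distribution")) fast_eq$probs else fast_eq
  a <- slow_propensity_per_fast_state
  if (length(p) != length(a))
    stop("dimension error: fast equilibrium and propensity vector differ in length")
  sum(p * a)
}

#' Construct a slow-scale (QSSA-reduced) model
#'
#' The fast subsystem enters only through `fast_equilibrium`, a function of
#' the slow state returning its conditional equilibrium distribution
#' (analytic, e.g. the two-state TF-binding law). Each slow reaction
#' specifies its state change `nu` over the slow species and its propensity
#' per fast state, a function of the slow state returning one rate per fast
#' state (constant vectors are accepted).
#'
#' @param species character vector of slow species names.
#' @param reactions list of lists with elements `nu` (integer change
#'   vector) and `rates_by_fast` (function(X_slow) -> numeric vector, or a
#'   numeric vector).
#' @param fast_equilibrium function(X_slow) -> `eq_distribution` or
#'   probability vector over fast states.
#' @return object of class `"eq_slow_model"`.
#' @export
slow_scale_model <- function(species, reactions, fast_equilibrium) {
  stopifnot(is.function(fast_equilibrium), length(reactions) >= 1)
  for (r in reactions) {
    if (length(r$nu) != length(species)) stop("slow reaction nu length mismatch")
  }
  structure(list(species = species, reactions = reactions,
                 fast_equilibrium = fast_equilibrium),
            class = "eq_slow_model")
}

#' Slow-scale SSA with QSSA-averaged propensities
#'
#' Gillespie simulation of the slow variables only: each slow reaction's
#' propensity is the QSSA average of its per-fast-state rates under the
#' fast equilibrium conditioned on the current slow state, recomputed (and
#' memoized per slow-state value) whenever the slow state changes.
#'
#' @param model an `eq_slow_model`.
#' @param X0_slow initial slow state.
#' @param t_end horizon.
#' @param seed integer seed.
#' @param max_steps guard.
#' @return an `eq_trajectory` over the slow species.
#' @export
slow_scale_ssa <- function(model, X0_slow, t_end, seed, max_steps = 1e6) {
  set.seed(seed)
  X <- as.integer(round(X0_slow))
  memo <- new.env(hash = TRUE, parent = emptyenv())
  eff_rates <- function(X) {
    k <- paste(X, collapse = ",")
    if (exists(k, envir = memo, inherits = FALSE)) return(get(k, envir = memo))
    fe <- tryCatch(model$fast_equilibrium(X), error = function(e)
      stop("fast-equilibrium provider failed at slow state (",
           paste(X, collapse = ","), "): ", conditionMessage(e)))
    a <- vapply(model$reactions, function(r) {
      v <- if (is.function(r$rates_by_fast)) r$rates_by_fast(X) else r$rates_by_fast
      averaged_propensity(fe, v)
    }, numeric(1))
    assign(k, a, envir = memo)
    a
  }
  t <- 0; times <- numeric(0); Xs <- list(X)
  repeat {
    a <- eff_rates(X)
    a0 <- sum(a)
    if (a0 <= 0) break
    tau <- rexp(1, a0)
    if (t + tau > t_end) break
    t <- t + tau
    h <- sample.int(length(a), 1, prob = a)
    X <- X + model$reactions[[h]]$nu
    times <- c(times, t)
    Xs[[length(Xs) + 1L]] <- X
    if (length(times) > max_steps)
      stop("step-limit error: slow-scale SSA exceeded max_steps")
  }
  states <- do.call(rbind, Xs)
  colnames(states) <- model$species
  structure(list(times = c(0, times), states = states, t_end = t_end,
                 species = model$species, seed = seed),
            class = "eq_trajectory")
}

#' Time-averaged mean of a species with batch-means standard error
#'
#' Splits `[burn_in, t_end]` into `batches` equal windows, computes the
#' time-weighted mean of the species in each, and returns the overall mean
#' with the batch-means standard error (appropriate for autocorrelated
#' occupancy estimates).
#'
#' @param traj an `eq_trajectory`.
#' @param species species name or column index.
#' @param burn_in discarded initial span.
#' @param batches number of batches (default 20).
#' @return list with `mean`, `se`, `batch_means`.
#' @export
batch_means <- function(traj, species, burn_in = 0, batches = 20) {
  stopifnot(traj$t_end > burn_in)
  col <- if (is.character(species)) match(species, traj$species) else species
  if (is.na(col)) stop("unknown species")
  edges <- seq(burn_in, traj$t_end, length.out = batches + 1)
  times <- c(traj$times, traj$t_end)
  vals <- traj$states[, col]
  bm <- numeric(batches)
  for (b in seq_len(batches)) {
    lo <- edges[b]; hi <- edges[b + 1]
    dur <- pmax(pmin(times[-1], hi) - pmax(times[-length(times)], lo), 0)
    bm[b] <- sum(dur * vals) / (hi - lo)
  }
  list(mean = mean(bm), se = sd(bm) / sqrt(batches), batch_means = bm)
}
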