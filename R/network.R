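#' @useDynLib eqmotif, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as is
#' @importFrom stats dpois dbinom qpois runif setNames optim rexp sd
#' @importFrom utils head tail read.delim write.table combn
NULL

#' Construct a reaction
#'
#' A reaction is an ordered pair of complexes (reactant `alpha`, product
#' `beta`) over the species of a network, together with a positive stochastic
#' rate constant `kappa`. Complexes are vectors of non-negative integer
#' stoichiometric coefficients. Rate constants are taken as already stochastic
#' (no volume conversion).
#'
#' Stochastic mass-action propensities are supported for reactions of order
#' at most two. Reactions of higher order (or non-mass-action kinetics) must
#' carry an explicit `propensity` function of the state vector.
#'
#' @param reactant integer vector of reactant coefficients (alpha).
#' @param product integer vector of product coefficients (beta), same length.
#' @param rate positive rate constant kappa.
#' @param propensity optional function(X) -> non-negative rate, overriding
#'   mass action. Required when `sum(reactant) > 2`.
#' @return an object of class `"eq_reaction"`.
#' @export
reaction <- function(reactant, product, rate, propensity = NULL) {
  reactant <- as.integer(round(reactant))
  product <- as.integer(round(product))
  if (length(reactant) != length(product))
    stop("reactant and product complexes must have equal length")
  if (any(reactant < 0L) || any(product < 0L))
    stop("complex coefficients must be non-negative integers")
  if (all(reactant == product))
    stop("reactant and product complexes must differ (alpha != beta)")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("rate constant must be a positive finite number")
  if (!is.null(propensity) && !is.function(propensity))
    stop("propensity must be NULL or a function of the state vector")
  structure(
    list(reactant = reactant, product = product, rate = as.numeric(rate),
         propensity = propensity),
    class = "eq_reaction")
}

#' Construct a reaction network
#'
#' Reactions with identical reactant and product complexes are merged by
#' summing their rate constants (identical Markov dynamics), except when an
#' explicit propensity rule is attached.
#'
#' @param species character vector of unique species names.
#' @param reactions list of [reaction()] objects over those species.
#' @return an object of class `"eq_network"` with elements `species`,
#'   `reactions`, and the derived stoichiometric matrix `nu` (n x m).
#' @export
reaction_network <- function(species, reactions) {
  species <- as.character(species)
  if (anyDuplicated(species)) stop("species names must be unique")
  if (length(reactions) == 0L) stop("network must contain at least one reaction")
  for (r in reactions) {
    if (!inherits(r, "eq_reaction")) stop("reactions must be built with reaction()")
    if (length(r$reactant) != length(species))
      stop("complex length must equal the number of species")
  }
  # merge duplicate (alpha, beta) pairs by summing kappa (mass-action only)
  keys <- vapply(reactions, function(r)
    paste(paste(r$reactant, collapse = ","), paste(r$product, collapse = ","),
          sep = ">"), character(1))
  keep <- !duplicated(keys)
  if (any(!keep)) {
    merged <- reactions[keep]
    for (i in which(!keep)) {
      j <- match(keys[i], keys[keep])
      if (is.null(reactions[[i]]$propensity) && is.null(merged[[j]]$propensity)) {
        merged[[j]]$rate <- merged[[j]]$rate + reactions[[i]]$rate
      } else {
        merged <- c(merged, reactions[i])  # keep distinct if custom kinetics
      }
    }
    reactions <- merged
  }
  nu <- vapply(reactions, function(r) as.integer(r$product - r$reactant),
               integer(length(species)))
  nu <- matrix(nu, nrow = length(species),
               dimnames = list(species, NULL))
  structure(list(species = species, reactions = reactions, nu = nu),
            class = "eq_network")
}

#' @export
print.eq_network <- function(x, ...) {
  cat(sprintf("Reaction network: %d species, %d reactions\n",
              length(x$species), length(x$reactions)))
  for (r in x$reactions) {
    cat(" ", format_complex(r$reactant, x$species), "->",
        format_complex(r$product, x$species),
        sprintf("; k=%g", r$rate),
        if (!is.null(r$propensity)) "[custom propensity]" else "", "\n")
  }
  invisible(x)
}

format_complex <- function(coefs, species) {
  nz <- which(coefs > 0L)
  if (length(nz) == 0L) return("0")
  paste(vapply(nz, function(i) {
    if (coefs[i] == 1L) species[i] else paste(coefs[i], species[i])
  }, character(1)), collapse = " + ")
}

#' Stochastic mass-action propensity of one reaction channel
#'
#' Returns the intensity a_j(X) at which channel `j` fires in state `X`.
#' The four supported mass-action left-hand sides give kappa (zeroth order),
#' kappa*X_i (first order), kappa*X_i*X_k (heterogeneous bimolecular) and
#' kappa*X_i*(X_i - 1) (homogeneous bimolecular). Note the homogeneous
#' bimolecular form carries NO factor 1/2: a dimerisation 2M -> D with N
#' monomers fires at kappa*N*(N-1). The propensity is zero whenever a
#' reactant count is below its stoichiometric requirement.
#'
#' @param network an `eq_network`.
#' @param j reaction index in `1:length(network$reactions)`.
#' @param X non-negative integer state vector.
#' @return a single non-negative number.
#' @export
propensity <- function(network, j, X) {
  r <- network$reactions[[j]]
  if (length(X) != length(network$species)) stop("state length mismatch")
  if (any(X < 0)) stop("state counts must be non-negative")
  if (!is.null(r$propensity)) {
    a <- r$propensity(X)
    if (!is.finite(a) || a < 0) stop("custom propensity returned invalid value")
    return(a)
  }
  ord <- sum(r$reactant)
  if (ord > 2L)
    stop("unsupported kinetics: order > 2 requires an explicit propensity rule")
  if (any(X < r$reactant)) return(0)
  a <- r$rate
  for (i in which(r$reactant > 0L)) {
    if (r$reactant[i] == 1L) a <- a * X[i]
    else a <- a * X[i] * (X[i] - 1)  # homogeneous bimolecular, no 1/2
  }
  a
}

# all propensities at state X (numeric vector of length m)
propensities <- function(network, X) {
  vapply(seq_along(network$reactions), function(j) propensity(network, j, X),
         numeric(1))
}

#' Stoichiometric matrix
#'
#' @param network an `eq_network`.
#' @return integer matrix nu with column j equal to beta_j - alpha_j.
#' @export
stoichiometric_matrix <- function(network) network$nu

#' Conservation laws (integer left nullspace of nu)
#'
#' Conservation laws are in one-to-one correspondence with left nullvectors
#' of the stoichiometric matrix: integer weight vectors w with w' nu = 0,
#' so that w'X is invariant under every reaction. Returns an integer basis
#' computed by exact fraction-free Gaussian elimination; the empty list when
#' nu has full row rank.
#'
#' @param network an `eq_network`.
#' @return list of integer weight vectors (possibly empty).
#' @export
conservation_laws <- function(network) {
  nu <- network$nu
  basis <- integer_left_nullspace(nu)
  lapply(seq_len(ncol(basis)), function(k) basis[, k])
}

# Exact integer basis of {w : w' A = 0} via rational RREF of t(A).
# Entries of A are small integers, so double arithmetic on integer-valued
# intermediates is exact here (fraction-free elimination keeps them integral).
integer_left_nullspace <- function(A) {
  M <- t(A)  # nullspace of M x = 0 over columns = species weights
  M <- apply(M, 2, as.numeric)
  M <- matrix(M, nrow = nrow(t(A)))
  m <- nrow(M); n <- ncol(M)
  # fraction-free (Bareiss-like) forward elimination
  piv_cols <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    p <- which(abs(M[row:m, col]) > 0.5)
    if (length(p) == 0L) next
    p <- p[1] + row - 1L
    if (p != row) M[c(p, row), ] <- M[c(row, p), ]
    for (r in seq_len(m)[-row]) {
      if (abs(M[r, col]) > 0.5) {
        g <- M[row, col]
        M[r, ] <- M[r, ] * g - M[row, ] * M[r, col]
        d <- gcd_vec(M[r, ])
        if (d > 1) M[r, ] <- M[r, ] / d
      }
    }
    piv_cols <- c(piv_cols, col)
    row <- row + 1L
  }
  free_cols <- setdiff(seq_len(n), piv_cols)
  out <- matrix(0, nrow = n, ncol = length(free_cols))
  for (k in seq_along(free_cols)) {
    fc <- free_cols[k]
    v <- numeric(n)
    v[fc] <- 1
    # back-substitute pivots: M[r, piv] * v[piv] + M[r, fc] * 1 = 0
    for (r in rev(seq_along(piv_cols))) {
      pc <- piv_cols[r]
      rhs <- -sum(M[r, -pc] * v[-pc])
      v[pc] <- rhs / M[r, pc]
    }
    # scale to integers
    den <- sapply(v, function(x) {
      if (abs(x - round(x)) < 1e-9) 1 else frac_den(x)
    })
    v <- v * Reduce(lcm2, den)
    v <- round(v)
    d <- gcd_vec(v)
    if (d > 1) v <- v / d
    if (sum(v) < 0) v <- -v
    out[, k] <- v
  }
  out
}

gcd2 <- function(a, b) { a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- a %% b; a <- b; b <- t }; max(a, 1) }
gcd_vec <- function(v) { v <- abs(v[abs(v) > 0.5]); if (!length(v)) return(1)
  Reduce(gcd2, v) }
lcm2 <- function(a, b) a / gcd2(a, b) * b
frac_den <- function(x, max_den = 1e6) {
  for (d in 1:1000) if (abs(x * d - round(x * d)) < 1e-9) return(d)
  stop("could not rationalize nullspace entry")
}

#' Enumerate one stoichiometric compatibility class
#'
#' Breadth-first closure of `X0` under all reactions applied in either
#' direction (state changes +nu_j and -nu_j, counts kept non-negative).
#' From each dequeued state the candidate neighbours are generated in
#' reaction-index order, forward displacements before backward ones, and
#' unseen states are appended in that order, giving a deterministic
#' enumeration with `X0` first.
#'
#' @param network an `eq_network`.
#' @param X0 initial state (non-negative integer vector).
#' @param max_states abort if the class exceeds this many states.
#' @return an object of class `"eq_space"`: list with `states` (matrix, one
#'   row per state) and a key-based index.
#' @export
enumerate_compatibility_class <- function(network, X0, max_states = 20000L) {
  X0 <- as.integer(round(X0))
  if (any(X0 < 0)) stop("initial state must be non-negative")
  if (length(X0) != length(network$species)) stop("state length mismatch")
  nu <- network$nu
  steps <- cbind(nu, -nu)  # forward then backward displacements
  key <- function(x) paste(x, collapse = ",")
  seen <- new.env(hash = TRUE, parent = emptyenv())
  states <- vector("list", 256L)
  states[[1L]] <- X0
  assign(key(X0), 1L, envir = seen)
  n_states <- 1L
  q_head <- 1L
  while (q_head <= n_states) {
    X <- states[[q_head]]
    for (s in seq_len(ncol(steps))) {
      Y <- X + steps[, s]
      if (any(Y < 0L)) next
      k <- key(Y)
      if (!exists(k, envir = seen, inherits = FALSE)) {
        n_states <- n_states + 1L
        if (n_states > max_states)
          stop("truncation required: compatibility class exceeds max_states; ",
               "use truncate_by_mass() or raise the bound")
        if (n_states > length(states)) length(states) <- 2L * length(states)
        states[[n_states]] <- Y
        assign(k, n_states, envir = seen)
      }
    }
    q_head <- q_head + 1L
  }
  S <- do.call(rbind, states[seq_len(n_states)])
  colnames(S) <- network$species
  new_space(S)
}

new_space <- function(S) {
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(S))) assign(paste(S[i, ], collapse = ","), i, envir = idx)
  structure(list(states = S, index = idx), class = "eq_space")
}

#' @export
print.eq_space <- function(x, ...) {
  cat(sprintf("State space with %d states over %d species\n",
              nrow(x$states), ncol(x$states)))
  invisible(x)
}

#' Number of states in a state space
#' @param space an `eq_space`.
#' @return integer count.
#' @export
n_states <- function(space) nrow(space$states)

state_index <- function(space, X) {
  k <- paste(X, collapse = ",")
  if (exists(k, envir = space$index, inherits = FALSE))
    get(k, envir = space$index) else NA_integer_
}

#' Build the generator (rate matrix) on an enumerated state space
#'
#' Column-generator convention: dP/dt = Q P, so Q[to, from] is the intensity
#' of the jump from state `from` to state `to`, the diagonal makes every
#' column sum to zero, and an equilibrium distribution is a right nullvector
#' of Q. Transitions that would leave a truncated space are dropped together
#' with their outgoing rate (reflecting truncation), keeping Q a proper
#' generator.
#'
#' @param network an `eq_network`.
#' @param space an `eq_space` closed under the reactions (or truncated).
#' @return sparse `dgCMatrix` Q.
#' @export
build_rate_matrix <- function(network, space) {
  S <- space$states
  N <- nrow(S)
  nu <- network$nu
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (from in seq_len(N)) {
    X <- S[from, ]
    for (j in seq_along(network$reactions)) {
      a <- propensity(network, j, X)
      if (a <= 0) next
      Y <- X + nu[, j]
      if (any(Y < 0L)) next
      to <- state_index(space, Y)
      if (is.na(to)) next  # reflecting truncation: drop transition and rate
      ii <- c(ii, to); jj <- c(jj, from); xx <- c(xx, a)
    }
  }
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::colSums(Q)
  Q
}

#' Truncate an infinite compatibility class by equilibrium mass
#'
#' Returns the smallest prefix (in enumeration order) of the class whose
#' equilibrium probability mass is at least `1 - eps`. For a pure
#' birth-death species (zeroth-order production, first-order decay) the
#' known Poisson(kappa_b/kappa_d) form fixes the cutoff by its tail
#' quantile; otherwise the space is grown geometrically and the reflecting
#' nullspace solution is used to estimate the tail mass.
#'
#' @param network an `eq_network`.
#' @param X0 initial state.
#' @param eps mass cutoff in (0, 1).
#' @param max_states growth guard.
#' @return an `eq_space` (the identity for finite classes).
#' @export
truncate_by_mass <- function(network, X0, eps, max_states = 20000L) {
  stopifnot(eps > 0, eps < 1)
  fin <- tryCatch(enumerate_compatibility_class(network, X0, max_states),
                  error = function(e) NULL)
  if (!is.null(fin)) return(fin)  # finite class: no truncation
  bd <- birth_death_parameters(network)
  if (!is.null(bd)) {
    lam <- bd$kb / bd$kd
    K <- qpois(1 - eps, lam)  # smallest K with P(X <= K) >= 1 - eps
    S <- matrix(0L:K, ncol = 1, dimnames = list(NULL, network$species))
    return(new_space(S))
  }
  # no analytic form: grow a count cap geometrically until the reflecting
  # equilibrium puts < eps mass on the boundary shell
  cap <- 16L
  repeat {
    sp <- enumerate_capped(network, X0, cap)
    if (nrow(sp$states) > max_states)
      stop("truncation failed: growth exceeded max_states without analytic form")
    Q <- build_rate_matrix(network, sp)
    eq <- equilibrium_nullspace(Q)[[1]]
    boundary <- apply(sp$states, 1, function(x) any(x >= cap))
    if (sum(eq$probs[boundary]) < eps) return(sp)
    cap <- cap * 2L
  }
}

# detect a single-species birth-death network: 0 -> S (kb), S -> 0 (kd)
birth_death_parameters <- function(network) {
  if (length(network$species) != 1L || length(network$reactions) != 2L)
    return(NULL)
  kb <- kd <- NA_real_
  for (r in network$reactions) {
    if (r$reactant == 0L && r$product == 1L) kb <- r$rate
    if (r$reactant == 1L && r$product == 0L) kd <- r$rate
  }
  if (is.na(kb) || is.na(kd)) return(NULL)
  list(kb = kb, kd = kd)
}

enumerate_capped <- function(network, X0, cap) {
  nu <- network$nu
  steps <- cbind(nu, -nu)
  key <- function(x) paste(x, collapse = ",")
  seen <- new.env(hash = TRUE, parent = emptyenv())
  states <- list(as.integer(X0))
  assign(key(X0), 1L, envir = seen)
  qh <- 1L
  while (qh <= length(states)) {
    X <- states[[qh]]
    for (s in seq_len(ncol(steps))) {
      Y <- X + steps[, s]
      if (any(Y < 0L) || any(Y > cap)) next
      k <- key(Y)
      if (!exists(k, envir = seen, inherits = FALSE)) {
        states[[length(states) + 1L]] <- Y
        assign(k, length(states), envir = seen)
      }
    }
    qh <- qh + 1L
  }
  S <- do.call(rbind, states)
  colnames(S) <- network$species
  new_space(S)
}
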