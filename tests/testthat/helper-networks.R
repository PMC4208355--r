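# Shared builders for test networks and generators of seeded random rates.

# tridiagonal path generator over states 0..N (column convention)
path_Q <- function(p, q) {
  N <- length(p)
  Q <- matrix(0, N + 1, N + 1)
  for (i in seq_len(N)) {
    Q[i + 1, i] <- p[i]   # i-1 -> i
    Q[i, i + 1] <- q[i]   # i -> i-1
  }
  diag(Q) <- -colSums(Q)
  Q
}

# cycle generator over states 1..N: p[i] = rate i -> i+1, q[i] = i -> i-1
cycle_Q <- function(p, q) {
  N <- length(p)
  Q <- matrix(0, N, N)
  for (i in seq_len(N)) {
    Q[i %% N + 1, i] <- p[i]
    Q[(i - 2) %% N + 1, i] <- q[i]
  }
  diag(Q) <- -colSums(Q)
  Q
}

rand_rates <- function(n, lo = 0.1, hi = 10) exp(runif(n, log(lo), log(hi)))

birth_death_network <- function(kb, kd) {
  reaction_network("S", list(reaction(0L, 1L, kb), reaction(1L, 0L, kd)))
}

# glue a path chain (r states) and a cycle (s states) at path end / cycle
# state 1, as one literal generator, for validating glue_equilibria
glued_Q <- function(pp, pq, cp, cq) {
  r <- length(pp) + 1L; s <- length(cp)
  n <- r + s - 1L
  Q <- matrix(0, n, n)
  for (i in seq_along(pp)) { Q[i + 1, i] <- pp[i]; Q[i, i + 1] <- pq[i] }
  cyc <- c(r, r + seq_len(s - 1L))  # global indices of the cycle states
  for (i in seq_len(s)) {
    Q[cyc[i %% s + 1], cyc[i]] <- Q[cyc[i %% s + 1], cyc[i]] + cp[i]
    Q[cyc[(i - 2) %% s + 1], cyc[i]] <- Q[cyc[(i - 2) %% s + 1], cyc[i]] + cq[i]
  }
  diag(Q) <- 0
  diag(Q) <- -colSums(Q)
  Q
}

oracle <- function(network, space) {
  equilibrium_nullspace(build_rate_matrix(network, space), space)[[1]]
}

max_abs_diff <- function(a, b) {
  pa <- if (inherits(a, "eq_distribution")) a$probs else a
  pb <- if (inherits(b, "eq_distribution")) b$probs else b
  max(abs(pa - pb))
}
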