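test_that("nullspace oracle solves small closed chains exactly", {
  expect_equal(equilibrium_nullspace(path_Q(1, 1))[[1]]$probs, c(0.5, 0.5))
  expect_equal(equilibrium_nullspace(path_Q(2, 3))[[1]]$probs, c(3, 2) / 5)
  expect_equal(equilibrium_nullspace(cycle_Q(rep(1, 4), rep(1, 4)))[[1]]$probs,
               rep(0.25, 4))
})

test_that("nullspace oracle returns one distribution per closed class", {
  # two disconnected 2-state chains in one generator
  Q <- matrix(0, 4, 4)
  Q[2, 1] <- 1; Q[1, 2] <- 2; Q[4, 3] <- 3; Q[3, 4] <- 1
  diag(Q) <- -colSums(Q)
  eqs <- equilibrium_nullspace(Q)
  expect_length(eqs, 2)
  supports <- lapply(eqs, function(e) which(e$probs > 0))
  expect_setequal(vapply(supports, paste, character(1), collapse = ","),
                  c("1,2", "3,4"))
  # transient states get no closed class of their own: A -> B <-> C
  Q2 <- matrix(0, 3, 3)
  Q2[2, 1] <- 1; Q2[3, 2] <- 1; Q2[2, 3] <- 1
  diag(Q2) <- -colSums(Q2)
  eqs2 <- equilibrium_nullspace(Q2)
  expect_length(eqs2, 1)
  expect_equal(eqs2[[1]]$probs, c(0, 0.5, 0.5))
})

test_that("path formula matches the oracle on seeded random paths", {
  set.seed(101)
  for (rep in 1:60) {
    N <- sample(1:20, 1)
    p <- rand_rates(N); q <- rand_rates(N)
    dist <- equilibrium_path(path_rates(p, q))
    orc <- equilibrium_nullspace(path_Q(p, q))[[1]]
    expect_lt(max_abs_diff(dist, orc), 1e-12)
    expect_lt(detailed_balance_residual(path_Q(p, q), dist), 1e-12)
  }
  expect_equal(equilibrium_path(path_rates(c(1, 1), c(1, 1)))$probs, rep(1, 3) / 3)
  expect_equal(equilibrium_path(path_rates(2, 1))$probs, c(1, 2) / 3)
  expect_error(equilibrium_path(path_rates(c(1, -1), c(1, 1))), "positive")
})

test_that("long paths are normalized stably (Horner scheme)", {
  # strongly forward-biased 300-state path: naive products overflow
  N <- 300
  p <- rep(1e4, N); q <- rep(1e-4, N)
  dist <- equilibrium_path(path_rates(p, q))
  expect_equal(sum(dist$probs), 1, tolerance = 1e-12)
  expect_gt(dist$probs[N + 1], 1 - 1e-7)
})

test_that("cycle formula matches oracle and Kirchhoff on seeded cycles", {
  set.seed(202)
  for (rep in 1:60) {
    N <- sample(3:8, 1)
    p <- rand_rates(N); q <- rand_rates(N)
    Q <- cycle_Q(p, q)
    cyc <- equilibrium_cycle(p, q)
    expect_lt(max_abs_diff(cyc, equilibrium_nullspace(Q)[[1]]), 1e-12)
    if (N <= 6)
      expect_lt(max_abs_diff(cyc, equilibrium_kirchhoff(Q)), 1e-12)
  }
  expect_equal(equilibrium_cycle(rep(2, 5), rep(2, 5))$probs, rep(0.2, 5))
  expect_error(equilibrium_cycle(c(1, 1), c(1, 1)), "at least 3")
})

test_that("Kirchhoff handles trees, zero intensities and guards size", {
  expect_equal(equilibrium_kirchhoff(path_Q(2, 3))$probs, c(3, 2) / 5)
  # irreversible 3-cycle: zero backward intensities, uniform if rates equal
  Q <- matrix(0, 3, 3)
  Q[2, 1] <- 1; Q[3, 2] <- 1; Q[1, 3] <- 1
  diag(Q) <- -colSums(Q)
  expect_equal(equilibrium_kirchhoff(Q)$probs, rep(1, 3) / 3)
  expect_lt(max_abs_diff(equilibrium_kirchhoff(Q),
                         equilibrium_nullspace(Q)[[1]]), 1e-12)
  # seeded random connected support graphs with <= 6 states
  set.seed(303)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    Q <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {           # random spanning tree
      j <- sample(seq_len(i), 1)
      Q[i + 1, j] <- rand_rates(1); Q[j, i + 1] <- rand_rates(1)
    }
    extra <- sample(n, 2)                  # plus one extra edge if distinct
    if (extra[1] != extra[2]) {
      Q[extra[1], extra[2]] <- rand_rates(1)
      Q[extra[2], extra[1]] <- rand_rates(1)
    }
    diag(Q) <- 0; diag(Q) <- -colSums(Q)
    expect_lt(max_abs_diff(equilibrium_kirchhoff(Q),
                           equilibrium_nullspace(Q)[[1]]), 1e-10)
  }
  expect_error(equilibrium_kirchhoff(diag(-1, 20) + diag(1, 20)[, c(2:20, 1)]),
               "too large|disconnected")
})

test_that("gluing reproduces the oracle of the literally glued chain", {
  expect_equal(glue_equilibria(c(.5, .5), c(.5, .5))$probs, rep(1, 3) / 3)
  # gluing with a point mass at the partner's glue vertex is the identity
  expect_equal(glue_equilibria(c(.3, .7), c(1))$probs, c(.3, .7))
  set.seed(404)
  for (rep in 1:50) {
    np <- sample(1:4, 1); nc <- sample(3:5, 1)
    pp <- rand_rates(np); pq <- rand_rates(np)
    cp <- rand_rates(nc); cq <- rand_rates(nc)
    pi1 <- equilibrium_path(path_rates(pp, pq))
    pi2 <- equilibrium_cycle(cp, cq)
    glued <- glue_equilibria(pi1, pi2)
    orc <- equilibrium_nullspace(glued_Q(pp, pq, cp, cq))[[1]]
    expect_lt(max_abs_diff(glued, orc), 1e-12)
  }
})

test_that("detailed balance holds on paths but fails on generic cycles", {
  p <- c(2, 1, 1); q <- c(1, 1, 1)   # breaks the Kolmogorov criterion
  Q <- cycle_Q(p, q)
  eq <- equilibrium_nullspace(Q)[[1]]
  expect_gt(detailed_balance_residual(Q, eq), 1e-6)
  # residual zero on a connected chain implies stationarity
  pr <- path_rates(c(1.7, 0.3), c(0.6, 2.2))
  dist <- equilibrium_path(pr)
  expect_lt(detailed_balance_residual(path_Q(pr$p, pr$q), dist), 1e-12)
})
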