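test_that("birth-death equilibrium is the truncated Poisson law", {
  m <- birth_death(1, 1, eps = 1e-12)
  expect_equal(m$closed_form$probs[1], exp(-1), tolerance = 1e-10)
  m2 <- birth_death(2, 1, eps = 1e-12)
  i <- m2$space$states[, 1]
  expect_equal(m2$closed_form$probs[i == 1], m2$closed_form$probs[i == 2])
  # truncated closed form vs nullspace of the reflecting-truncated generator
  eps <- 1e-8
  m3 <- birth_death(3, 2, eps = eps)
  orc <- oracle(m3$network, m3$space)
  expect_lt(max_abs_diff(m3$closed_form, orc), 10 * eps)
})

test_that("isomerization equilibrium is binomial and oracle-consistent", {
  m <- isomerization(2, 1, 1)
  expect_equal(m$closed_form$probs, c(.25, .5, .25))
  expect_equal(isomerization(1, 3, 1)$closed_form$probs, c(.25, .75))
  set.seed(21)
  for (rep in 1:20) {
    N <- sample(1:12, 1); k <- rand_rates(2)
    m <- isomerization(N, k[1], k[2])
    expect_lt(max_abs_diff(m$closed_form, oracle(m$network, m$space)), 1e-12)
  }
})

test_that("tf_binding follows the printed recursion and the oracle", {
  # N=2, T=3, unit rates: recursion kappa_u(i+1) pi_{i+1} = kappa_b(N-i)(T-i) pi_i
  # gives unnormalized (1, 6, 6) (oracle-confirmed)
  m <- tf_binding(2, 3, 1, 1)
  expect_equal(m$closed_form$probs, c(1, 6, 6) / 13)
  expect_lt(max_abs_diff(m$closed_form, oracle(m$network, m$space)), 1e-14)
  set.seed(22)
  for (rep in 1:20) {
    T_tf <- sample(2:10, 1); N <- sample(1:T_tf, 1); k <- rand_rates(2)
    m <- tf_binding(N, T_tf, k[1], k[2])
    expect_lt(max_abs_diff(m$closed_form, oracle(m$network, m$space)), 1e-12)
  }
  # N > T swaps the roles of gene and TF
  expect_message(ms <- tf_binding(5, 2, 1.3, 0.7), "interchanging")
  expect_equal(ms$closed_form$probs, tf_binding(2, 5, 1.3, 0.7)$closed_form$probs)
})

test_that("dimerization path has the parity-dependent rates", {
  m <- dimerization(2, 1, 1)   # p_0 = 2 kappa_b, q_1 = kappa_u
  expect_equal(m$closed_form$probs, c(1, 2) / 3)
  set.seed(23)
  for (total in c(4, 5, 7, 10)) {
    k <- rand_rates(2)
    m <- dimerization(total, k[1], k[2])
    expect_lt(max_abs_diff(m$closed_form, oracle(m$network, m$space)), 1e-12)
  }
  expect_error(dimerization(1, 1, 1), "at least 2")
})

test_that("single-gene motif is Bernoulli with a Hill-1 response", {
  expect_equal(single_gene_tf(0, 1, 1)$parameterization$pr_bound, 0)
  expect_equal(single_gene_tf(4, 0.25, 1)$closed_form$probs, c(.5, .5))
  # Hill coefficient 1: Pr/(1-Pr) is exactly linear in T
  pb <- function(T_tf) single_gene_tf(T_tf, 2, 3)$parameterization$pr_bound
  odds <- function(x) x / (1 - x)
  expect_equal(odds(pb(8)) / odds(pb(4)), 2, tolerance = 1e-12)
  # monotone in T and in kappa_b/kappa_u
  expect_true(all(diff(vapply(1:20, pb, numeric(1))) > 0))
  pr_k <- vapply(c(.5, 1, 2, 4), function(kb)
    single_gene_tf(5, kb, 1)$parameterization$pr_bound, numeric(1))
  expect_true(all(diff(pr_k) > 0))
  # specialization: tf_binding(1, T) is the same Bernoulli
  expect_equal(tf_binding(1, 7, 1.2, 0.4)$closed_form$probs,
               single_gene_tf(7, 1.2, 0.4)$closed_form$probs)
})

test_that("sequential two-site path, helpers and degenerate top state", {
  m <- sequential_two_sites(2, 1, 1, 1, 1)
  expect_equal(m$closed_form$probs, c(1, 2, 2) / 5)
  expect_lt(max_abs_diff(m$closed_form, oracle(m$network, m$space)), 1e-14)
  set.seed(24)
  for (rep in 1:20) {
    T_tf <- sample(2:9, 1); k <- rand_rates(4)
    m <- sequential_two_sites(T_tf, k[1], k[2], k[3], k[4])
    expect_lt(max_abs_diff(m$closed_form, oracle(m$network, m$space)), 1e-12)
  }
  # helper molecules rescale the first binding propensity by H
  mh <- sequential_two_sites(3, 1, 1, 1, 1, helpers = 4)
  expect_lt(max_abs_diff(mh$closed_form, oracle(mh$network, mh$space)), 1e-12)
  expect_equal(mh$closed_form$probs,
               sequential_two_sites(3, 4, 1, 1, 1)$closed_form$probs)
  # kappa_1 = 0: the fully bound state is unreachable
  md <- sequential_two_sites(3, 1, 0, 1, 1)
  expect_lt(max_abs_diff(md$closed_form, oracle(md$network, md$space)), 1e-12)
  expect_equal(md$closed_form$probs[3], 0)
})

test_that("independent two-site cycle: closed form, oracle, and limits", {
  set.seed(25)
  for (rep in 1:20) {
    T_tf <- sample(2:9, 1); k <- rand_rates(4)
    m <- independent_two_sites(T_tf, k[1], k[2], k[3], k[4])
    expect_lt(max_abs_diff(m$closed_form, oracle(m$network, m$space)), 1e-12)
    # symmetric case agrees with the general cycle formula
    # (cycle order: free, A, both, B)
    p <- c(k[1] * T_tf, k[2] * (T_tf - 1), k[4], k[3])
    q <- c(k[1] * T_tf, k[3], k[4], k[2] * (T_tf - 1))
    cyc <- equilibrium_cycle(p, q)$probs
    expect_lt(max(abs(m$closed_form$probs - cyc[c(1, 2, 4, 3)])), 1e-12)
  }
  # strong unbinding concentrates mass on the free state
  m <- independent_two_sites(2, 1, 1, 1e6, 1e6)
  expect_gt(m$closed_form$probs[1], 0.999)
  # the four-state cycle generally breaks detailed balance for some rates:
  # make the two sites non-equivalent by comparing against a perturbed cycle
  p <- c(2, 1, 1, 1); q <- c(1, 1, 1, 1)
  eq <- equilibrium_nullspace(cycle_Q(p, q))[[1]]
  expect_gt(detailed_balance_residual(cycle_Q(p, q), eq), 1e-6)
})

test_that("hypercube compounding equals the N-copy chain and its oracle", {
  # N=2, T=2: aggregate the explicit two-site (hypercube) model by occupancy
  full <- independent_two_sites(2, 1, 1, 1, 1)
  orc <- oracle(full$network, full$space)
  agg <- c(orc$probs[1], orc$probs[2] + orc$probs[3], orc$probs[4])
  comp <- hypercube_compounded(2, 2, 1, 1)
  expect_lt(max(abs(agg - comp$closed_form$probs)), 1e-12)
  # non-cooperative case is exactly tf_binding
  expect_equal(hypercube_compounded(3, 7, 1.5, 0.8)$closed_form$probs,
               tf_binding(3, 7, 1.5, 0.8)$closed_form$probs)
  # cooperative rates follow the stated p_i, q_i path
  set.seed(26)
  for (rep in 1:10) {
    N <- sample(2:4, 1); T_tf <- N + sample(0:4, 1)
    kv <- rand_rates(N); km <- rand_rates(N)
    m <- hypercube_compounded(N, T_tf, 1, 1, kappa_vec = kv,
                              kappa_minus_vec = km)
    i <- 0:(N - 1)
    orc <- equilibrium_nullspace(
      path_Q(kv * (N - i) * (T_tf - i), km * (i + 1)))[[1]]
    expect_lt(max_abs_diff(m$closed_form, orc), 1e-12)
    expect_lt(max_abs_diff(m$closed_form, oracle(m$network, m$space)), 1e-12)
  }
})

test_that("glued three-site motifs match their oracles in both variants", {
  set.seed(27)
  for (rep in 1:15) {
    T_tf <- sample(3:8, 1); k <- rand_rates(6)
    for (v in c("path_cycle", "cycle_path")) {
      m <- glued_three_sites(T_tf, k[1], k[2], k[3], k[4], k[5], k[6],
                             variant = v)
      expect_equal(n_states(m$space), 5)
      expect_lt(max_abs_diff(m$closed_form, oracle(m$network, m$space)), 1e-12)
    }
  }
  # strong unbinding at the unique first site collapses to the unbound state
  m <- glued_three_sites(4, 1, 1e7, 1, 1, 1, 1, variant = "path_cycle")
  expect_gt(m$closed_form$probs[1], 0.999)
})
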