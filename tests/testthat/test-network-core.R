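test_that("mass-action propensities follow the four stochastic forms", {
  net <- reaction_network(c("M", "D", "G", "F"), list(
    reaction(c(0, 0, 0, 0) + c(0, 0, 0, 0), c(1, 0, 0, 0), 3),    # 0 -> M
    reaction(c(2, 0, 0, 0), c(0, 1, 0, 0), 2),                    # 2M -> D
    reaction(c(0, 0, 1, 1), c(0, 0, 0, 0) + c(0, 1, 0, 0), 1.5),  # G+F -> D
    reaction(c(1, 0, 0, 0), c(0, 0, 0, 1), 0.5)))                 # M -> F
  X <- c(5, 0, 1, 4)
  expect_equal(propensity(net, 1, X), 3)                # zeroth order
  expect_equal(propensity(net, 2, X), 2 * 5 * 4)        # kappa X (X-1), no 1/2
  expect_equal(propensity(net, 3, X), 1.5 * 1 * 4)      # kappa Xi Xj
  expect_equal(propensity(net, 4, X), 0.5 * 5)          # first order
  # insufficient reactants give zero
  expect_equal(propensity(net, 2, c(1, 0, 1, 4)), 0)
  expect_equal(propensity(net, 3, c(5, 0, 0, 4)), 0)
})

test_that("reactions above order two require an explicit propensity rule", {
  expect_error(
    propensity(reaction_network("A", list(reaction(3L, 0L, 1))), 1, 5L),
    "unsupported kinetics")
  # with a rule, arbitrary kinetics are admitted
  net <- reaction_network("A", list(
    reaction(3L, 0L, 1, propensity = function(X) X[1]^3),
    reaction(0L, 3L, 1)))
  expect_equal(propensity(net, 1, 4L), 64)
})

test_that("duplicate reactions are merged by summing rate constants", {
  net <- reaction_network("A", list(
    reaction(1L, 0L, 2), reaction(1L, 0L, 3), reaction(0L, 1L, 1)))
  expect_length(net$reactions, 2)
  expect_equal(propensity(net, 1, 1L), 5)
})

test_that("stoichiometric matrix columns are beta - alpha", {
  iso <- reaction_network(c("S1", "S2"), list(
    reaction(c(1, 0), c(0, 1), 1), reaction(c(0, 1), c(1, 0), 1)))
  expect_equal(unname(stoichiometric_matrix(iso)),
               matrix(c(-1, 1, 1, -1), 2))
  bd <- birth_death_network(1, 1)
  expect_equal(unname(stoichiometric_matrix(bd)), matrix(c(1, -1), 1))
  lad <- dimer_tf_network(5, 1, 1, 1, 1)
  expect_equal(unname(stoichiometric_matrix(lad$network)),
               cbind(c(-2, 1, 0, 0), c(2, -1, 0, 0),
                     c(0, -1, -1, 1), c(0, 1, 1, -1)))
})

test_that("conservation laws are an exact integer left-null basis", {
  iso <- isomerization(3, 1, 1)$network
  laws <- conservation_laws(iso)
  expect_length(laws, 1)
  expect_equal(laws[[1]], c(1, 1))
  expect_length(conservation_laws(birth_death_network(1, 1)), 0)
  lad <- dimer_tf_network(6, 1, 1, 1, 1)
  laws <- conservation_laws(lad$network)
  expect_length(laws, 2)
  # exact annihilation and span equal to {(1,2,0,2), (0,0,1,1)}
  for (w in laws) expect_true(all(w %*% lad$network$nu == 0))
  B <- do.call(cbind, laws)
  target <- cbind(c(1, 2, 0, 2), c(0, 0, 1, 1))
  expect_equal(qr(cbind(B, target))$rank, 2)
})

test_that("compatibility classes enumerate deterministically and respect laws", {
  iso <- isomerization(2, 1, 1)
  expect_equal(n_states(iso$space), 3)
  expect_equal(iso$space$states[, "S1"], 0:2)
  lad <- dimer_tf_network(5, 1, 1, 1, 1)
  expect_equal(n_states(lad$space), 5)
  # every state satisfies the conservation laws fixed by X0
  laws <- conservation_laws(lad$network)
  for (w in laws) {
    vals <- lad$space$states %*% w
    expect_true(all(vals == vals[1]))
  }
  sg <- single_gene_tf(3, 1, 1)
  expect_equal(n_states(sg$space), 2)
  expect_error(enumerate_compatibility_class(birth_death_network(1, 1), 0L,
                                             max_states = 50),
               "truncation required")
})

test_that("rate matrices are proper column generators", {
  two <- path_Q(2, 3)
  expect_equal(two, matrix(c(-2, 2, 3, -3), 2))
  set.seed(11)
  for (rep in 1:10) {
    fx <- generate_fixture(sample(c("path", "cycle", "glued", "ladder"), 1),
                           sample(3:8, 1), seed = rep)
    Q <- build_rate_matrix(fx$network, fx$space)
    expect_lt(max(abs(Matrix::colSums(Q))), 1e-14)
    Qd <- as.matrix(Q); diag(Qd) <- 0
    expect_true(all(Qd >= 0))
  }
})

test_that("mass truncation matches the Poisson tail oracle", {
  bd <- birth_death_network(1, 1)
  sp <- truncate_by_mass(bd, 0L, eps = 1e-12)
  K <- max(sp$states)
  expect_lt(1 - ppois(K, 1), 1e-12)          # kept mass >= 1 - eps
  expect_gte(1 - ppois(K - 1, 1), 1e-12)     # and K is the smallest such
  # eps = 0.5 keeps only {0, 1}: e^-1 + e^-1 ~ 0.7358 >= 0.5
  sp2 <- truncate_by_mass(bd, 0L, eps = 0.5)
  expect_equal(as.integer(sp2$states[, 1]), c(0L, 1L))
  # finite classes come back unchanged
  iso <- isomerization(2, 1, 1)
  expect_equal(n_states(truncate_by_mass(iso$network, c(0L, 2L), 1e-6)), 3)
})
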