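test_that("complex graphs deduplicate nodes deterministically", {
  iso <- isomerization(2, 1, 1)$network
  cg <- complex_graph(iso)
  expect_equal(nrow(cg$complexes), 2)
  expect_equal(nrow(cg$edges), 2)
  bd <- birth_death_network(1, 1)
  cg <- complex_graph(bd)
  expect_equal(nrow(cg$complexes), 2)   # the empty complex and S
  lad <- dimer_tf_network(5, 1, 1, 1, 1)$network
  expect_equal(nrow(complex_graph(lad)$complexes), 4)  # 2M, D, G+D, G*
})

test_that("CRNT reports: linkage classes, weak reversibility, deficiency", {
  lad <- dimer_tf_network(5, 1, 1, 1, 1)$network
  rep_ <- crnt_report(lad)
  expect_equal(rep_$n_complexes, 4)
  expect_equal(rep_$n_linkage_classes, 2)
  expect_equal(rep_$stoich_dim, 2)
  expect_equal(rep_$deficiency, 0)
  expect_true(rep_$weakly_reversible)

  iso <- isomerization(2, 1, 1)$network
  rep_ <- crnt_report(iso)
  expect_equal(rep_$deficiency, 2 - 1 - 1)
  expect_true(rep_$weakly_reversible)

  # irreversible chain A -> B -> C is not weakly reversible
  chain <- reaction_network(c("A", "B", "C"), list(
    reaction(c(1, 0, 0), c(0, 1, 0), 1),
    reaction(c(0, 1, 0), c(0, 0, 1), 1)))
  expect_false(crnt_report(chain)$weakly_reversible)

  # deficiency is non-negative across the fixture families
  set.seed(31)
  for (rep in 1:8) {
    fx <- generate_fixture(sample(c("path", "cycle", "glued", "ladder"), 1),
                           sample(3:7, 1), seed = 100 + rep)
    expect_gte(crnt_report(fx$network)$deficiency, 0)
  }
})

test_that("complex-balanced states solve the per-complex balance equations", {
  iso <- isomerization(2, 1, 1)$network
  cb <- complex_balanced_state(iso)
  expect_lt(cb$residual, 1e-10)
  expect_equal(unname(cb$c[1] / cb$c[2]), 1, tolerance = 1e-8)

  # monomer-dimer: c_D / c_M^2 = kappa_1 / kappa_minus1 on the balance manifold
  md <- reaction_network(c("M", "D"), list(
    reaction(c(2, 0), c(0, 1), 3), reaction(c(0, 1), c(2, 0), 2)))
  cb <- complex_balanced_state(md)
  expect_equal(unname(cb$c["D"] / cb$c["M"]^2), 3 / 2, tolerance = 1e-8)

  lad <- dimer_tf_network(6, 2, 3, 1.5, 0.7)$network
  cb <- complex_balanced_state(lad)
  expect_lt(cb$residual, 1e-10)
  # the complex-balanced state zeroes the deterministic rate equation
  expect_lt(max(abs(ode_rate_residual(lad, cb$c))), 1e-9)
  # extended relation: c_G c_D kappa_b = c_G* kappa_u
  expect_equal(unname(cb$c["G"] * cb$c["D"] * 1.5 / (cb$c["Gs"] * 0.7)), 1,
               tolerance = 1e-8)
})

test_that("product-form equilibrium conditions Poissons on the class", {
  # isomerization conditioned on X1 + X2 = N is Binomial(N, c1/(c1+c2))
  m <- isomerization(5, 2, 1)
  cb <- complex_balanced_state(m$network)
  pf <- product_form_equilibrium(m$network, cb, m$space)
  expect_lt(max_abs_diff(pf, m$closed_form), 1e-10)
  # dimerization class matches the path closed form
  dm <- dimerization(7, 1.4, 0.6)
  conc <- c(M = 1, D = 1.4 / 0.6)   # analytic complex-balanced state
  pf <- product_form_equilibrium(dm$network, conc, dm$space)
  expect_lt(max_abs_diff(pf, dm$closed_form), 1e-12)
  expect_error(product_form_equilibrium(dm$network, c(1, -1), dm$space),
               "positive")
})

test_that("conditional product form is invariant to the choice of c", {
  dm <- dimerization(8, 1.4, 0.6)
  # the balance manifold is c_D = (kappa_1/kappa_minus1) c_M^2, any c_M > 0
  for (cm in c(0.3, 1, 4)) {
    conc <- c(M = cm, D = 1.4 / 0.6 * cm^2)
    pf <- product_form_equilibrium(dm$network, conc, dm$space)
    expect_lt(max_abs_diff(pf, dm$closed_form), 1e-12)
  }
  lad <- dimer_tf_network(6, 2, 1, 1, 1)
  base <- NULL
  for (cm in c(0.5, 2)) {
    conc <- c(M = cm, D = 2 * cm^2, G = 1, Gs = 2 * cm^2 * 1 / 1)
    pf <- product_form_equilibrium(lad$network, conc, lad$space)
    if (is.null(base)) base <- pf else expect_lt(max_abs_diff(pf, base), 1e-12)
  }
})

test_that("weakly reversible deficiency-zero fixtures get exact product forms", {
  set.seed(32)
  for (rep in 1:10) {
    fx <- generate_fixture("ladder", sample(4:10, 1), seed = 200 + rep)
    rep_ <- crnt_report(fx$network)
    expect_true(rep_$weakly_reversible && rep_$deficiency == 0)
    cb <- complex_balanced_state(fx$network)
    pf <- product_form_equilibrium(fx$network, cb, fx$space)
    expect_lt(max_abs_diff(pf, oracle(fx$network, fx$space)), 1e-10)
  }
})
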