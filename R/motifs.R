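# Catalogue of named biochemical motifs. Every constructor returns both the
# explicit reaction network (for oracle / SSA use) and the closed-form
# equilibrium distribution on the motif's canonical compatibility class.

motif_result <- function(network, space, closed_form, parameterization) {
  if (n_states(space) != length(closed_form$probs))
    stop("closed form must live on the motif's state space")
  structure(list(network = network, space = space, closed_form = closed_form,
                 parameterization = parameterization),
            class = "eq_motif")
}

#' @export
print.eq_motif <- function(x, ...) {
  cat("Motif:", paste(names(x$parameterization),
                      unlist(x$parameterization), sep = "=", collapse = " "), "\n")
  print(x$network)
  cat("Closed-form equilibrium over", n_states(x$space), "states:\n")
  print(signif(x$closed_form$probs, 6))
  invisible(x)
}

#' Birth-death process (constitutive production and degradation)
#'
#' 0 -> S at rate kappa_b, S -> 0 at intensity kappa_d * X. The equilibrium
#' is Poisson(kappa_b/kappa_d); the returned closed form is that Poisson
#' law renormalized on the eps-mass-truncated state space \{0..K\}.
#'
#' @param kappa_b,kappa_d positive rate constants.
#' @param eps truncation mass cutoff in (0, 1).
#' @return an `eq_motif`.
#' @export
birth_death <- function(kappa_b, kappa_d, eps = 1e-12) {
  net <- reaction_network("S", list(
    reaction(0L, 1L, kappa_b),
    reaction(1L, 0L, kappa_d)))
  space <- truncate_by_mass(net, 0L, eps)
  lam <- kappa_b / kappa_d
  w <- dpois(space$states[, 1], lam)
  motif_result(net, space, equilibrium_distribution(w / sum(w)),
               list(kappa_b = kappa_b, kappa_d = kappa_d, eps = eps,
                    lambda = lam))
}

#' Isomerization of N molecules between two states
#'
#' S2 -> S1 at constant kappa_plus per molecule, S1 -> S2 at kappa_minus.
#' With i the count of S1, the transition rates are p_i = kappa_plus (N - i)
#' and q_i = kappa_minus i; detailed balance yields the binomial law
#' Binomial(N, kappa_plus / (kappa_plus + kappa_minus)) over i. This is also
#' a coarse model for the Goldbeter-Koshland switch with effective rates
#' kappa_plus' E1 and kappa_minus' E2.
#'
#' @param N total molecule count (>= 1).
#' @param kappa_plus,kappa_minus positive rate constants.
#' @return an `eq_motif`; states ordered by increasing i = count of S1.
#' @export
isomerization <- function(N, kappa_plus, kappa_minus) {
  stopifnot(N >= 1)
  net <- reaction_network(c("S1", "S2"), list(
    reaction(c(0L, 1L), c(1L, 0L), kappa_plus),   # S2 -> S1
    reaction(c(1L, 0L), c(0L, 1L), kappa_minus))) # S1 -> S2
  space <- enumerate_compatibility_class(net, c(0L, N))
  p <- kappa_plus / (kappa_plus + kappa_minus)
  probs <- dbinom(space$states[, "S1"], N, p)
  motif_result(net, space, equilibrium_distribution(probs),
               list(N = N, kappa_plus = kappa_plus, kappa_minus = kappa_minus,
                    p = p))
}

#' TF binding to N copies of a gene by T transcription factors
#'
#' G + F -> G* at kappa_b, G* -> G + F at kappa_u, with N total gene copies
#' and T total TFs. With i the number of complexes, p_i =
#' kappa_b (N - i)(T - i) and q_i = kappa_u i; the equilibrium is the
#' detailed-balance path distribution with the Horner-normalized product
#' pi_i propto prod_{k<i} p_k / q_{k+1}. For N > T the roles of gene and TF
#' are interchanged automatically (a message is emitted).
#'
#' @param N gene copy number, `1 <= N`.
#' @param T_tf total TF count.
#' @param kappa_b,kappa_u binding / unbinding rate constants.
#' @return an `eq_motif`; states ordered by increasing bound count i.
#' @export
tf_binding <- function(N, T_tf, kappa_b, kappa_u) {
  stopifnot(N >= 1, T_tf >= 1)
  if (N > T_tf) {
    message("tf_binding: N > T, interchanging the roles of gene and TF")
    tmp <- N; N <- T_tf; T_tf <- tmp
  }
  net <- reaction_network(c("G", "Gs", "F"), list(
    reaction(c(1L, 0L, 1L), c(0L, 1L, 0L), kappa_b),
    reaction(c(0L, 1L, 0L), c(1L, 0L, 1L), kappa_u)))
  space <- enumerate_compatibility_class(net, c(N, 0L, T_tf))
  i <- 0:(N - 1)
  dist <- equilibrium_path(path_rates(kappa_b * (N - i) * (T_tf - i),
                                      kappa_u * (i + 1)))
  motif_result(net, space, dist,
               list(N = N, T = T_tf, kappa_b = kappa_b, kappa_u = kappa_u))
}

#' Protein dimerization and dissociation
#'
#' 2M -> D at kappa_b (propensity kappa_b M (M - 1), no factor 1/2),
#' D -> 2M at kappa_u. With total monomer count 2N (even) or 2N + 1 (odd)
#' and i the dimer count, p_i = kappa_b (2N - 2i)(2N - 2i - 1) in the even
#' case, p_i = kappa_b (2N + 1 - 2i)(2N - 2i) in the odd case, and
#' q_i = kappa_u i.
#'
#' @param total_monomers total monomer mass M + 2D (>= 2).
#' @param kappa_b,kappa_u positive rate constants.
#' @return an `eq_motif`; states ordered by increasing dimer count.
#' @export
dimerization <- function(total_monomers, kappa_b, kappa_u) {
  if (total_monomers < 2) stop("total_monomers must be at least 2")
  net <- reaction_network(c("M", "D"), list(
    reaction(c(2L, 0L), c(0L, 1L), kappa_b),
    reaction(c(0L, 1L), c(2L, 0L), kappa_u)))
  space <- enumerate_compatibility_class(net, c(as.integer(total_monomers), 0L))
  N <- total_monomers %/% 2
  i <- 0:(N - 1)
  p <- if (total_monomers %% 2 == 0)
    kappa_b * (2 * N - 2 * i) * (2 * N - 2 * i - 1)
  else
    kappa_b * (2 * N + 1 - 2 * i) * (2 * N - 2 * i)
  dist <- equilibrium_path(path_rates(p, kappa_u * (i + 1)))
  motif_result(net, space, dist,
               list(total_monomers = total_monomers, N = N,
                    kappa_b = kappa_b, kappa_u = kappa_u))
}

#' Single gene regulated by one of T TFs (two-state motif)
#'
#' The N = 1 specialization of [tf_binding()]: Pr(bound) =
#' kappa_b T / (kappa_u + kappa_b T), a Hill function of T with Hill
#' coefficient 1.
#'
#' @param T_tf total TF count (>= 0).
#' @param kappa_b,kappa_u binding / unbinding rate constants.
#' @return an `eq_motif`; state order (free, bound).
#' @export
single_gene_tf <- function(T_tf, kappa_b, kappa_u) {
  stopifnot(T_tf >= 0)
  net <- reaction_network(c("G", "Gs", "F"), list(
    reaction(c(1L, 0L, 1L), c(0L, 1L, 0L), kappa_b),
    reaction(c(0L, 1L, 0L), c(1L, 0L, 1L), kappa_u)))
  space <- enumerate_compatibility_class(net, c(1L, 0L, as.integer(T_tf)))
  pb <- if (T_tf == 0) 0 else kappa_b * T_tf / (kappa_u + kappa_b * T_tf)
  probs <- if (n_states(space) == 1L) 1 else c(1 - pb, pb)
  motif_result(net, space, equilibrium_distribution(probs),
               list(T = T_tf, kappa_b = kappa_b, kappa_u = kappa_u,
                    pr_bound = pb))
}

#' Gene with two ordered (sequential) TF binding sites
#'
#' A single gene with two non-overlapping TFBSs that must be occupied in a
#' fixed order. The three-state path over bound count i in \{0, 1, 2\} has
#' rates p_0 = kappa_0 T, p_1 = kappa_1 (T - 1), q_1 = kappa_minus1,
#' q_2 = kappa_minus2, and equilibrium (1, p_0/q_1, p_0 p_1/(q_1 q_2)) up to
#' normalization. When the first binding is facilitated by one of H helper
#' molecules the first binding propensity is rescaled by H (`helpers = H`).
#' `kappa_1 = 0` is admitted and gives the degenerate chain with the top
#' state unreachable (probability 0).
#'
#' @param T_tf total TF count (>= 2 for the full path).
#' @param kappa_0,kappa_1 first / second binding rate constants.
#' @param kappa_minus1,kappa_minus2 first / second unbinding rate constants.
#' @param helpers optional helper-molecule count H >= 1 rescaling the first
#'   binding propensity.
#' @return an `eq_motif`; states ordered by bound count.
#' @export
sequential_two_sites <- function(T_tf, kappa_0, kappa_1, kappa_minus1,
                                 kappa_minus2, helpers = 1) {
  stopifnot(T_tf >= 1, helpers >= 1)
  k0_eff <- kappa_0 * helpers
  reactions <- list(
    reaction(c(1L, 0L, 0L, 1L), c(0L, 1L, 0L, 0L), k0_eff),       # G0+F -> G1
    reaction(c(0L, 1L, 0L, 0L), c(1L, 0L, 0L, 1L), kappa_minus1)) # G1 -> G0+F
  if (kappa_1 > 0 && T_tf >= 2) {
    reactions <- c(reactions, list(
      reaction(c(0L, 1L, 0L, 1L), c(0L, 0L, 1L, 0L), kappa_1),
      reaction(c(0L, 0L, 1L, 0L), c(0L, 1L, 0L, 1L), kappa_minus2)))
  } else if (kappa_minus2 > 0 && T_tf >= 2) {
    # degenerate chain: top state present in the class but unreachable upward
    reactions <- c(reactions, list(
      reaction(c(0L, 0L, 1L, 0L), c(0L, 1L, 0L, 1L), kappa_minus2)))
  }
  net <- reaction_network(c("G0", "G1", "G2", "F"), reactions)
  space <- enumerate_compatibility_class(net, c(1L, 0L, 0L, as.integer(T_tf)))
  p0 <- k0_eff * T_tf
  w <- c(1, p0 / kappa_minus1)
  if (n_states(space) == 3L) {
    p1 <- kappa_1 * (T_tf - 1)
    w <- c(w, w[2] * p1 / kappa_minus2)
  }
  motif_result(net, space, equilibrium_distribution(w / sum(w)),
               list(T = T_tf, kappa_0 = kappa_0, kappa_1 = kappa_1,
                    kappa_minus1 = kappa_minus1, kappa_minus2 = kappa_minus2,
                    helpers = helpers))
}

#' Gene with two independent TF binding sites (four-state cycle)
#'
#' A single gene with two non-overlapping TFBSs occupied in either order by
#' identical TFs: the state space is the cycle free -> A -> both -> B ->
#' free. Under the symmetric-rate assumption (the same kappa_0, kappa_1,
#' kappa_minus1, kappa_minus2 for both sites; cooperativity still possible
#' through kappa_0 != kappa_1) the Kolmogorov criterion holds and the
#' closed form is the detailed-balance solution
#' (1, a, a, a b) / C with a = kappa_0 T / kappa_minus1 and
#' b = kappa_1 (T - 1) / kappa_minus2. The general non-symmetric cycle is
#' available through [equilibrium_cycle()].
#'
#' @param T_tf total TF count (>= 2).
#' @param kappa_0,kappa_1 first / second binding rate constants.
#' @param kappa_minus1,kappa_minus2 first / second unbinding rate constants.
#' @return an `eq_motif`; state order (free, site-A, site-B, both).
#' @export
independent_two_sites <- function(T_tf, kappa_0, kappa_1, kappa_minus1,
                                  kappa_minus2) {
  stopifnot(T_tf >= 2)
  net <- reaction_network(c("G00", "G10", "G01", "G11", "F"), list(
    reaction(c(1L, 0L, 0L, 0L, 1L), c(0L, 1L, 0L, 0L, 0L), kappa_0),
    reaction(c(0L, 1L, 0L, 0L, 0L), c(1L, 0L, 0L, 0L, 1L), kappa_minus1),
    reaction(c(1L, 0L, 0L, 0L, 1L), c(0L, 0L, 1L, 0L, 0L), kappa_0),
    reaction(c(0L, 0L, 1L, 0L, 0L), c(1L, 0L, 0L, 0L, 1L), kappa_minus1),
    reaction(c(0L, 1L, 0L, 0L, 1L), c(0L, 0L, 0L, 1L, 0L), kappa_1),
    reaction(c(0L, 0L, 0L, 1L, 0L), c(0L, 1L, 0L, 0L, 1L), kappa_minus2),
    reaction(c(0L, 0L, 1L, 0L, 1L), c(0L, 0L, 0L, 1L, 0L), kappa_1),
    reaction(c(0L, 0L, 0L, 1L, 0L), c(0L, 0L, 1L, 0L, 1L), kappa_minus2)))
  space <- enumerate_compatibility_class(net, c(1L, 0L, 0L, 0L, as.integer(T_tf)))
  a <- kappa_0 * T_tf / kappa_minus1
  b <- kappa_1 * (T_tf - 1) / kappa_minus2
  w <- c(1, a, a, a * b)  # order: free, A, B, both (BFS order)
  motif_result(net, space, equilibrium_distribution(w / sum(w)),
               list(T = T_tf, kappa_0 = kappa_0, kappa_1 = kappa_1,
                    kappa_minus1 = kappa_minus1, kappa_minus2 = kappa_minus2))
}

#' N independent binding sites, compounded over occupancy (hypercube)
#'
#' Independent binding and unbinding of TFs to N sites of one gene lives on
#' an N-dimensional hypercube; compounding the C(N, i) vertices with i TFs
#' bound gives a path over i in \{0..N\} with p_i = kappa_b (N - i)(T - i)
#' and q_i = kappa_u i - the same chain as N gene copies binding one TF
#' each, so the non-cooperative closed form equals [tf_binding()]. With
#' occupancy-dependent (cooperative) constants the rates become
#' p_i = kappa_vec\[i+1\] (N - i)(T - i) and q_i = kappa_minus_vec\[i\] i.
#'
#' @param N_sites number of binding sites, `1 <= N_sites <= T_tf`.
#' @param T_tf total TF count.
#' @param kappa_b,kappa_u non-cooperative rate constants.
#' @param kappa_vec,kappa_minus_vec optional length-N vectors of
#'   occupancy-dependent binding / unbinding constants (cooperative case).
#' @return an `eq_motif` over compounded occupancy classes; the network in
#'   the cooperative case uses explicit per-reaction propensity rules on a
#'   (bound, unbound) site representation.
#' @export
hypercube_compounded <- function(N_sites, T_tf, kappa_b, kappa_u,
                                 kappa_vec = NULL, kappa_minus_vec = NULL) {
  stopifnot(N_sites >= 1, N_sites <= T_tf)
  cooperative <- !is.null(kappa_vec) || !is.null(kappa_minus_vec)
  if (!cooperative) {
    res <- tf_binding(N_sites, T_tf, kappa_b, kappa_u)
    res$parameterization$compounded <- TRUE
    return(res)
  }
  if (length(kappa_vec) != N_sites || length(kappa_minus_vec) != N_sites)
    stop("cooperative constants must be vectors of length N_sites")
  N <- N_sites
  # species (B, U): bound and unbound site counts, B + U = N conserved
  bind <- function(X) {
    i <- X[1]
    if (i >= N) 0 else kappa_vec[i + 1] * (N - i) * (T_tf - i)
  }
  unbind <- function(X) {
    i <- X[1]
    if (i <= 0) 0 else kappa_minus_vec[i] * i
  }
  net <- reaction_network(c("B", "U"), list(
    reaction(c(0L, 1L), c(1L, 0L), 1, propensity = bind),
    reaction(c(1L, 0L), c(0L, 1L), 1, propensity = unbind)))
  space <- enumerate_compatibility_class(net, c(0L, N))
  i <- 0:(N - 1)
  dist <- equilibrium_path(path_rates(kappa_vec * (N - i) * (T_tf - i),
                                      kappa_minus_vec * (i + 1)))
  motif_result(net, space, dist,
               list(N = N, T = T_tf, cooperative = TRUE))
}

#' Gene with three TFBSs built by gluing two state spaces
#'
#' Two five-state examples assembled with the one-vertex gluing rule.
#' Variant `"path_cycle"`: one site must bind the first TF (two-state
#' chain), after which the remaining two sites bind independently
#' (four-state cycle glued at the singly-bound state). Variant
#' `"cycle_path"` is the mirror image: two sites bind the first two TFs in
#' any order (cycle), then the third site binds the last TF (two-state
#' chain glued at the doubly-bound state). Rates are symmetric across
#' interchangeable sites, as in the worked examples.
#'
#' @param T_tf total TF count (>= 3).
#' @param kappa_b1,kappa_u1 binding/unbinding constants for the first stage.
#' @param kappa_b2,kappa_u2 second stage.
#' @param kappa_b3,kappa_u3 third stage.
#' @param variant `"path_cycle"` or `"cycle_path"`.
#' @return an `eq_motif` over 5 states in breadth-first order.
#' @export
glued_three_sites <- function(T_tf, kappa_b1, kappa_u1, kappa_b2, kappa_u2,
                              kappa_b3, kappa_u3,
                              variant = c("path_cycle", "cycle_path")) {
  stopifnot(T_tf >= 3)
  variant <- match.arg(variant)
  T_tf <- as.integer(T_tf)
  if (variant == "path_cycle") {
    # species: G- (empty), GA (unique site bound), GAB, GAC, GABC, F
    net <- reaction_network(c("G0", "GA", "GAB", "GAC", "GABC", "F"), list(
      reaction(c(1,0,0,0,0,1), c(0,1,0,0,0,0), kappa_b1),
      reaction(c(0,1,0,0,0,0), c(1,0,0,0,0,1), kappa_u1),
      reaction(c(0,1,0,0,0,1), c(0,0,1,0,0,0), kappa_b2),
      reaction(c(0,0,1,0,0,0), c(0,1,0,0,0,1), kappa_u2),
      reaction(c(0,1,0,0,0,1), c(0,0,0,1,0,0), kappa_b2),
      reaction(c(0,0,0,1,0,0), c(0,1,0,0,0,1), kappa_u2),
      reaction(c(0,0,1,0,0,1), c(0,0,0,0,1,0), kappa_b3),
      reaction(c(0,0,0,0,1,0), c(0,0,1,0,0,1), kappa_u3),
      reaction(c(0,0,0,1,0,1), c(0,0,0,0,1,0), kappa_b3),
      reaction(c(0,0,0,0,1,0), c(0,0,0,1,0,1), kappa_u3)))
    space <- enumerate_compatibility_class(net, c(1L,0L,0L,0L,0L,T_tf))
    pi1 <- equilibrium_distribution(
      c(1, kappa_b1 * T_tf / kappa_u1) / (1 + kappa_b1 * T_tf / kappa_u1))
    r <- kappa_b2 * (T_tf - 1) / kappa_u2
    s <- kappa_b3 * (T_tf - 2) / kappa_u3
    w2 <- c(1, r, r, r * s)
    pi2 <- equilibrium_distribution(w2 / sum(w2))  # order: A, AB, AC, ABC
    dist <- glue_equilibria(pi1, pi2)              # order: G0, A, AB, AC, ABC
  } else {
    # species: G0, GA, GB, GAB, GABC, F (sites A, B interchangeable first)
    net <- reaction_network(c("G0", "GA", "GB", "GAB", "GABC", "F"), list(
      reaction(c(1,0,0,0,0,1), c(0,1,0,0,0,0), kappa_b1),
      reaction(c(0,1,0,0,0,0), c(1,0,0,0,0,1), kappa_u1),
      reaction(c(1,0,0,0,0,1), c(0,0,1,0,0,0), kappa_b1),
      reaction(c(0,0,1,0,0,0), c(1,0,0,0,0,1), kappa_u1),
      reaction(c(0,1,0,0,0,1), c(0,0,0,1,0,0), kappa_b2),
      reaction(c(0,0,0,1,0,0), c(0,1,0,0,0,1), kappa_u2),
      reaction(c(0,0,1,0,0,1), c(0,0,0,1,0,0), kappa_b2),
      reaction(c(0,0,0,1,0,0), c(0,0,1,0,0,1), kappa_u2),
      reaction(c(0,0,0,1,0,1), c(0,0,0,0,1,0), kappa_b3),
      reaction(c(0,0,0,0,1,0), c(0,0,0,1,0,1), kappa_u3)))
    space <- enumerate_compatibility_class(net, c(1L,0L,0L,0L,0L,T_tf))
    a <- kappa_b1 * T_tf / kappa_u1
    b <- kappa_b2 * (T_tf - 1) / kappa_u2
    w1 <- c(1, a, a, a * b)                        # order: G0, A, B, AB
    pi1 <- equilibrium_distribution(w1 / sum(w1))
    c3 <- kappa_b3 * (T_tf - 2) / kappa_u3
    pi2 <- equilibrium_distribution(c(1, c3) / (1 + c3))  # order: AB, ABC
    dist <- glue_equilibria(pi1, pi2)              # order: G0, A, B, AB, ABC
  }
  motif_result(net, space, dist,
               list(T = T_tf, variant = variant,
                    kappa_b1 = kappa_b1, kappa_u1 = kappa_u1,
                    kappa_b2 = kappa_b2, kappa_u2 = kappa_u2,
                    kappa_b3 = kappa_b3, kappa_u3 = kappa_u3))
}
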