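# Gene regulated by dimer transcription factors on a ladder-shaped state
# space: 2M <-> D (kappa_1 / kappa_minus1) and G + D <-> G* (kappa_b /
# kappa_u), with T total monomers (T = M + 2D + 2G*) and one gene copy
# (G + G* = 1). The state is (d_total, gene), d_total counting dimers
# whether free or bound; one side of the ladder is one state longer.

#' Dimer-TF gene regulation network and its ladder state space
#'
#' @param T_mono total monomer count T >= 2.
#' @param kappa_1,kappa_minus1 dimerization / dissociation constants.
#' @param kappa_b,kappa_u gene binding / unbinding constants.
#' @return list with `network` (species M, D, G, Gs), `space` (the ladder
#'   compatibility class of (T, 0, 1, 0), of size 2 floor(T/2) + 1) and
#'   `conservation` (the recovered conservation laws).
#' @export
dimer_tf_network <- function(T_mono, kappa_1, kappa_minus1, kappa_b, kappa_u) {
  if (T_mono < 2) stop("T must be at least 2 for binding to be reachable")
  net <- reaction_network(c("M", "D", "G", "Gs"), list(
    reaction(c(2L, 0L, 0L, 0L), c(0L, 1L, 0L, 0L), kappa_1),
    reaction(c(0L, 1L, 0L, 0L), c(2L, 0L, 0L, 0L), kappa_minus1),
    reaction(c(0L, 1L, 1L, 0L), c(0L, 0L, 0L, 1L), kappa_b),
    reaction(c(0L, 0L, 0L, 1L), c(0L, 1L, 1L, 0L), kappa_u)))
  space <- enumerate_compatibility_class(net, c(as.integer(T_mono), 0L, 1L, 0L))
  list(network = net, space = space, conservation = conservation_laws(net))
}

# log unnormalized product-form weights of the two ladder sides, using the
# complex-balanced state c_M = 1, c_D = kappa_1/kappa_minus1, c_G = 1,
# c_Gs = kappa_b c_D / kappa_u. Returns log S0 terms (gene free, d = 0..K)
# and log S1 terms (gene bound, d_total = 1..K), K = floor(T/2).
ladder_log_terms <- function(T_mono, kappa_1, kappa_minus1, kappa_b, kappa_u) {
  K <- T_mono %/% 2
  log_cD <- log(kappa_1) - log(kappa_minus1)
  d0 <- 0:K
  l0 <- d0 * log_cD - lgamma(d0 + 1) - lgamma(T_mono - 2 * d0 + 1)
  d1 <- seq_len(K)
  log_cGs <- log(kappa_b) + log_cD - log(kappa_u)
  l1 <- (d1 - 1) * log_cD - lgamma(d1) - lgamma(T_mono - 2 * d1 + 1) + log_cGs
  list(free = l0, bound = l1, K = K)
}

#' Exact probability that the gene is free (dimer-TF model)
#'
#' Computed by the product-form route: the complex-balanced steady state
#' exists (the network is reversible with deficiency zero), the conditional
#' product-of-Poissons equilibrium is evaluated on the ladder class in log
#' space, and the gene marginal is obtained by summing over total dimer
#' counts. Pr_T(G* = 1) is 1 minus the returned value.
#'
#' @inheritParams dimer_tf_network
#' @return Pr_T(G* = 0) in (0, 1).
#' @export
exact_gene_free_prob <- function(T_mono, kappa_1, kappa_minus1,
                                 kappa_b, kappa_u) {
  lt <- ladder_log_terms(T_mono, kappa_1, kappa_minus1, kappa_b, kappa_u)
  lfree <- logsumexp(lt$free)
  lbound <- logsumexp(lt$bound)
  1 / (1 + exp(lbound - lfree))
}

#' Full exact ladder equilibrium (product-form route)
#'
#' @inheritParams dimer_tf_network
#' @return list with `dist` (an `eq_distribution` on the ladder space) and
#'   the `space` itself, ordered as enumerated by [dimer_tf_network()].
#' @export
exact_ladder_equilibrium <- function(T_mono, kappa_1, kappa_minus1,
                                     kappa_b, kappa_u) {
  lad <- dimer_tf_network(T_mono, kappa_1, kappa_minus1, kappa_b, kappa_u)
  conc <- c(M = 1, D = kappa_1 / kappa_minus1, G = 1,
            Gs = kappa_b * kappa_1 / (kappa_minus1 * kappa_u))
  dist <- product_form_equilibrium(lad$network, conc, lad$space)
  list(dist = dist, space = lad$space, network = lad$network)
}

#' Asymptotic probability that the gene is free (saddle-point formula)
#'
#' Large-T approximation Pr_T(G* = 0) = 2 kappa_u / (kappa_b T), obtained
#' from the product-form marginal sums: both gene marginals are
#' coefficients of exp(c_D z^2 + z), the saddle point gives the odds
#' Pr(G* = 0)/Pr(G* = 1) = 2 kappa_u / (kappa_b (T - m*)) with m* the
#' O(sqrt(T)) deterministic monomer count, and the method's error terms
#' absorb both the kappa_1/kappa_minus1-dependent sqrt(T) correction and
#' the difference between the odds and the probability. The formula is
#' deliberately a function of kappa_b, kappa_u and T only; it may exceed 1
#' when T < 2 kappa_u / kappa_b, in which case it is clipped to \[0, 1\]
#' with a warning (increasing T always removes the need for clipping).
#'
#' @param T_mono total monomer count T >= 2.
#' @param kappa_b,kappa_u gene binding / unbinding constants.
#' @return clipped probability in \[0, 1\].
#' @export
asymptotic_gene_free_prob <- function(T_mono, kappa_b, kappa_u) {
  stopifnot(T_mono >= 2)
  val <- 2 * kappa_u / (kappa_b * T_mono)
  if (val > 1) {
    warning(sprintf(
      "asymptotic formula predicts %.3g > 1 at T = %d; clipping to 1 (increase T)",
      val, as.integer(T_mono)))
    val <- 1
  }
  max(0, min(1, val))
}

#' Deterministic steady-state dimer count
#'
#' Closed-form solution of kappa_1 m^2 = kappa_minus1 d with m + 2d = T:
#' m* = (-kappa_minus1 + sqrt(kappa_minus1^2 + 8 kappa_1 kappa_minus1 T)) /
#' (4 kappa_1) and d* = (T - m*)/2, which is almost the maximum possible
#' T/2 corrected by a term of order sqrt(T) depending on
#' kappa_1/kappa_minus1.
#'
#' @param T_mono total monomer count.
#' @param kappa_1,kappa_minus1 dimerization / dissociation constants.
#' @return steady-state dimer count d* (real).
#' @export
ode_steady_state_dimers <- function(T_mono, kappa_1, kappa_minus1) {
  stopifnot(T_mono >= 2)
  m <- (-kappa_minus1 +
          sqrt(kappa_minus1^2 + 8 * kappa_1 * kappa_minus1 * T_mono)) /
    (4 * kappa_1)
  (T_mono - m) / 2
}
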