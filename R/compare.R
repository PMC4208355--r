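# Comparison of four gene-regulation mechanisms: full-occupancy probability
# as a function of the TF count, power series of the occupancy deficit in
# 1/T, and the sequential/independent structural equivalence.

mechanisms <- c("monomer", "dimer", "sequential", "independent")

#' Full-occupancy probability curve of a regulation mechanism
#'
#' Probability that all TFBSs of a single gene are occupied, as a function
#' of the total TF (or monomer) count T:
#' * `monomer`: one site, Pr = kappa_b T / (kappa_u + kappa_b T);
#' * `dimer`: dimer TFs on the ladder; exact product-form marginal
#'   Pr(G* = 1) by default, the clipped saddle-point asymptotic with
#'   `asymptotic = TRUE`;
#' * `sequential`: two ordered sites, top state of the three-state path;
#' * `independent`: two independent sites, doubly-bound state of the
#'   four-state cycle (symmetric rates).
#'
#' @param mechanism one of `"monomer"`, `"dimer"`, `"sequential"`,
#'   `"independent"`.
#' @param T_grid increasing integer vector of TF counts (each >= the
#'   mechanism minimum: 1, 2, 2, 2 respectively).
#' @param rates named list: `kappa_b`, `kappa_u` (monomer, dimer; dimer
#'   additionally `kappa_1`, `kappa_minus1`), or `kappa_0`, `kappa_1`,
#'   `kappa_minus1`, `kappa_minus2` (sequential, independent).
#' @param asymptotic use the dimer asymptotic formula instead of the exact
#'   ladder marginal.
#' @return object of class `"eq_occupancy_curve"`: `mechanism`, `T`,
#'   `prob`.
#' @export
occupancy_curve <- function(mechanism, T_grid, rates, asymptotic = FALSE) {
  if (!mechanism %in% mechanisms)
    stop("unknown mechanism tag: ", mechanism)
  T_grid <- as.integer(T_grid)
  if (is.unsorted(T_grid, strictly = TRUE)) stop("T grid must be increasing")
  prob <- vapply(T_grid, function(T_tf) occupancy_prob(mechanism, T_tf, rates,
                                                       asymptotic), numeric(1))
  structure(list(mechanism = mechanism, T = T_grid, prob = prob,
                 rates = rates),
            class = "eq_occupancy_curve")
}

occupancy_prob <- function(mechanism, T_tf, rates, asymptotic = FALSE) {
  r <- rates
  switch(mechanism,
    monomer = {
      stopifnot(T_tf >= 1)
      r$kappa_b * T_tf / (r$kappa_u + r$kappa_b * T_tf)
    },
    dimer = {
      stopifnot(T_tf >= 2)
      if (asymptotic)
        1 - asymptotic_gene_free_prob(T_tf, r$kappa_b, r$kappa_u)
      else
        1 - exact_gene_free_prob(T_tf, r$kappa_1, r$kappa_minus1,
                                 r$kappa_b, r$kappa_u)
    },
    sequential = {
      stopifnot(T_tf >= 2)
      m <- sequential_two_sites(T_tf, r$kappa_0, r$kappa_1,
                                r$kappa_minus1, r$kappa_minus2)
      m$closed_form$probs[3]
    },
    independent = {
      stopifnot(T_tf >= 2)
      m <- independent_two_sites(T_tf, r$kappa_0, r$kappa_1,
                                 r$kappa_minus1, r$kappa_minus2)
      m$closed_form$probs[4]
    })
}

# ratio of two polynomials in T as a power series in u = 1/T.
# num, den: coefficient vectors, num[k] multiplies T^(k-1).
poly_ratio_series <- function(num, den, order) {
  dn <- length(num) - 1L; dd <- length(den) - 1L
  # num(T)/den(T) = u^(dd-dn) * N(u)/D(u), N(u) = rev(num) padded, D(u) = rev(den)
  shift <- dd - dn
  if (shift < 0) stop("deficit must vanish as T grows (deg num < deg den)")
  N <- rev(num); D <- rev(den)
  # power-series division N(u)/D(u) to enough terms
  terms <- order - shift + 1L
  if (terms < 1L) return(numeric(0))
  q <- numeric(terms)
  rsd <- c(N, numeric(max(0, terms - length(N))))
  for (k in seq_len(terms)) {
    q[k] <- rsd[k] / D[1]
    upto <- min(length(rsd), k + length(D) - 1L)
    if (upto >= k) {
      span <- k:upto
      rsd[span] <- rsd[span] - q[k] * D[seq_along(span)]
    }
  }
  # coefficient of u^j overall, j = 1..order (deficits start at 1/T)
  out <- numeric(order)
  for (k in seq_len(terms)) {
    j <- shift + k - 1L
    if (j >= 1 && j <= order) out[j] <- q[k]
  }
  out
}

#' Power series of the full-occupancy deficit in 1/T
#'
#' Expands 1 - Pr(fully bound), an exact rational function of T for the
#' monomer, sequential and independent mechanisms, as a power series in
#' u = 1/T to the requested order (arbitrary precision). The dimer
#' mechanism's occupancy is known only through the leading-order
#' saddle-point asymptotic, so only `order = 1` is available there
#' (coefficient 2 kappa_u / kappa_b); higher orders raise an
#' unsupported-precision error. Leading terms: monomer kappa_u/kappa_b;
#' sequential kappa_minus2/kappa_1; independent 2 kappa_minus2/kappa_1
#' (the factor 2 reflecting independent release).
#'
#' @param mechanism mechanism tag.
#' @param rates named rate list as in [occupancy_curve()].
#' @param order highest power of 1/T (>= 1).
#' @return numeric vector of coefficients of u^1..u^order.
#' @export
series_expansion <- function(mechanism, rates, order = 3) {
  stopifnot(order >= 1)
  if (!mechanism %in% mechanisms) stop("unknown mechanism tag: ", mechanism)
  r <- rates
  switch(mechanism,
    monomer = {
      # deficit = kappa_u / (kappa_u + kappa_b T)
      poly_ratio_series(num = c(r$kappa_u),
                        den = c(r$kappa_u, r$kappa_b), order)
    },
    dimer = {
      if (order > 1)
        stop("unsupported precision: the dimer mechanism admits only the ",
             "leading-order (1/T) coefficient")
      2 * r$kappa_u / r$kappa_b
    },
    sequential = {
      # weights (q1 q2, p0 q2, p0 p1), p0 = k0 T, p1 = k1 (T - 1)
      # deficit = (q1 q2 + k0 q2 T) / (q1 q2 + k0 q2 T + k0 k1 T (T-1))
      q1 <- r$kappa_minus1; q2 <- r$kappa_minus2
      k0 <- r$kappa_0; k1 <- r$kappa_1
      num <- c(q1 * q2, k0 * q2)
      den <- c(q1 * q2, k0 * q2 - k0 * k1, k0 * k1)
      poly_ratio_series(num, den, order)
    },
    independent = {
      # weights (q1 q2, 2 k0 q2 T (x2 states), k0 k1 T (T-1) * q? ) from
      # (1, a, a, ab), a = k0 T/q1, b = k1 (T-1)/q2, scaled by q1 q2:
      # deficit = (q1 q2 + 2 k0 q2 T) / (q1 q2 + 2 k0 q2 T + k0 k1 T (T-1))
      q1 <- r$kappa_minus1; q2 <- r$kappa_minus2
      k0 <- r$kappa_0; k1 <- r$kappa_1
      num <- c(q1 * q2, 2 * k0 * q2)
      den <- c(q1 * q2, 2 * k0 * q2 - k0 * k1, k0 * k1)
      poly_ratio_series(num, den, order)
    })
}

#' Sequential / independent two-site equivalence
#'
#' Halving kappa_0 and kappa_minus2 in the independent (cycle) model and
#' summing the probabilities of its two singly-bound states yields exactly
#' the sequential (path) model's three-state distribution. Returns whether
#' the identity holds to 1e-12 together with the maximal deviation.
#'
#' @param T_tf total TF count (>= 2).
#' @param rates named list with `kappa_0`, `kappa_1`, `kappa_minus1`,
#'   `kappa_minus2`.
#' @param rescale apply the factor-1/2 rescaling (default TRUE; FALSE
#'   exhibits the generic inequality).
#' @return list with `equivalent` (logical) and `max_deviation`.
#' @export
sequential_independent_equivalence <- function(T_tf, rates, rescale = TRUE) {
  r <- rates
  seqm <- sequential_two_sites(T_tf, r$kappa_0, r$kappa_1,
                               r$kappa_minus1, r$kappa_minus2)
  k0 <- if (rescale) r$kappa_0 / 2 else r$kappa_0
  km2 <- if (rescale) r$kappa_minus2 / 2 else r$kappa_minus2
  ind <- independent_two_sites(T_tf, k0, r$kappa_1, r$kappa_minus1, km2)
  pi_ind <- ind$closed_form$probs
  agg <- c(pi_ind[1], pi_ind[2] + pi_ind[3], pi_ind[4])
  dev <- max(abs(agg - seqm$closed_form$probs))
  list(equivalent = dev < 1e-12, max_deviation = dev)
}
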