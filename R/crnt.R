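# Chemical reaction network theory: complex graph, linkage classes, weak
# reversibility, deficiency, complex-balanced steady states, and the
# product-of-Poissons stochastic equilibrium they induce.

#' Complex graph of a reaction network
#'
#' Nodes are the distinct complexes (vectors over species, deduplicated in
#' first-occurrence order across reactant then product sides, reaction by
#' reaction); there is a directed edge for each reaction channel from its
#' reactant to its product complex.
#'
#' @param network an `eq_network`.
#' @return list with `complexes` (matrix, one row per complex) and `edges`
#'   (two-column matrix of node indices, one row per reaction).
#' @export
complex_graph <- function(network) {
  key <- function(v) paste(v, collapse = ",")
  nodes <- list(); idx <- new.env(hash = TRUE, parent = emptyenv())
  get_node <- function(v) {
    k <- key(v)
    if (!exists(k, envir = idx, inherits = FALSE)) {
      nodes[[length(nodes) + 1L]] <<- v
      assign(k, length(nodes), envir = idx)
    }
    get(k, envir = idx)
  }
  edges <- t(vapply(network$reactions, function(r)
    c(get_node(r$reactant), get_node(r$product)), integer(2)))
  cx <- do.call(rbind, nodes)
  colnames(cx) <- network$species
  list(complexes = cx, edges = edges)
}

#' Structural CRNT report
#'
#' Computes the number of complexes, the linkage classes (connected
#' components of the complex graph viewed as undirected), weak
#' reversibility (every linkage class strongly connected), the dimension of
#' the stoichiometric subspace dim Im(nu), and the deficiency
#' n_complexes - n_linkage_classes - stoich_dim (a non-negative integer).
#' Weak reversibility together with deficiency zero guarantees, for any
#' positive rate constants, a complex-balanced steady state in every
#' stoichiometric compatibility class (deficiency zero theorem).
#'
#' @param network an `eq_network`.
#' @return object of class `"eq_crnt_report"`.
#' @export
crnt_report <- function(network) {
  cg <- complex_graph(network)
  nc <- nrow(cg$complexes)
  g <- igraph::make_empty_graph(nc, directed = TRUE)
  g <- igraph::add_edges(g, as.vector(t(cg$edges)))
  weak <- igraph::components(g, mode = "weak")
  strong <- igraph::components(g, mode = "strong")
  # weakly reversible <=> weak and strong components coincide
  wr <- weak$no == strong$no
  sdim <- qr(network$nu)$rank
  defic <- nc - weak$no - sdim
  structure(list(n_complexes = as.integer(nc),
                 n_linkage_classes = as.integer(weak$no),
                 stoich_dim = as.integer(sdim),
                 deficiency = as.integer(defic),
                 weakly_reversible = wr),
            class = "eq_crnt_report")
}

#' @export
print.eq_crnt_report <- function(x, ...) {
  cat(sprintf(paste0("complexes: %d\nlinkage classes: %d\n",
                     "stoichiometric subspace dim: %d\ndeficiency: %d\n",
                     "weakly reversible: %s\n"),
              x$n_complexes, x$n_linkage_classes, x$stoich_dim, x$deficiency,
              x$weakly_reversible))
  invisible(x)
}

#' Find a complex-balanced steady state of the deterministic model
#'
#' Solves, in log-concentration space, the per-complex balance equations
#' sum_\{j: alpha_j = zeta\} kappa_j c^alpha_j =
#' sum_\{j: beta_j = zeta\} kappa_j c^alpha_j for every complex zeta, i.e.
#' every complex is generated at the same rate as it is consumed.
#' Deterministic monomials c^alpha are used (not falling factorials): the
#' deterministic complex-balanced state couples to the stochastic product
#' form through Theorem-style correspondences, and the mismatch with the
#' stochastic falling-factorial propensities is intentional. Root-finding
#' uses BFGS on the summed squared relative residuals with 10 seeded
#' multistarts. Any single complex-balanced state is returned: the choice
#' within/across compatibility classes is free and does not affect the
#' conditional stochastic equilibrium.
#'
#' @param network an `eq_network`.
#' @param tol relative residual tolerance for convergence.
#' @return list with positive concentration vector `c` and `residual`.
#' @export
complex_balanced_state <- function(network, tol = 1e-10) {
  rep_ <- crnt_report(network)
  if (!(rep_$weakly_reversible && rep_$deficiency == 0))
    warning("network is not weakly reversible with deficiency zero; ",
            "a complex-balanced state is not guaranteed to exist")
  cg <- complex_graph(network)
  n <- length(network$species)
  kappa <- vapply(network$reactions, `[[`, numeric(1), "rate")
  alpha <- vapply(network$reactions, `[[`, integer(n), "reactant")
  alpha <- matrix(alpha, nrow = n)
  resid_vec <- function(logc) {
    mono <- exp(drop(crossprod(alpha, logc)))  # c^alpha_j per reaction
    flux <- kappa * mono
    out <- numeric(nrow(cg$complexes))
    for (z in seq_along(out)) {
      produced <- sum(flux[cg$edges[, 2] == z])
      consumed <- sum(flux[cg$edges[, 1] == z])
      out[z] <- (produced - consumed) / max(produced + consumed, 1e-300)
    }
    out
  }
  obj <- function(logc) sum(resid_vec(logc)^2)
  best <- NULL
  for (s in 1:10) {
    start <- if (s == 1) rep(0, n) else {
      set.seed(1000 + s)
      runif(n, -2, 2)
    }
    fit <- tryCatch(
      optim(start, obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-16)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    if (!is.null(best) && sqrt(best$value) < tol) break
  }
  if (is.null(best) || max(abs(resid_vec(best$par))) > tol)
    stop("no complex-balanced state found after multistart ",
         "(consistent with deficiency > 0 or lack of weak reversibility)")
  conc <- exp(best$par)
  names(conc) <- network$species
  list(c = conc, residual = max(abs(resid_vec(best$par))))
}

#' Deterministic mass-action reaction-rate residual
#'
#' Right-hand side of dc/dt = nu (kappa * c^alpha) at `conc`; zero at any
#' steady state, in particular at every complex-balanced state.
#'
#' @param network an `eq_network`.
#' @param conc positive concentration vector.
#' @return numeric vector, one entry per species.
#' @export
ode_rate_residual <- function(network, conc) {
  n <- length(network$species)
  kappa <- vapply(network$reactions, `[[`, numeric(1), "rate")
  alpha <- matrix(vapply(network$reactions, `[[`, integer(n), "reactant"),
                  nrow = n)
  mono <- exp(drop(crossprod(alpha, log(conc))))
  drop(network$nu %*% (kappa * mono))
}

#' Product-form Poisson equilibrium on a compatibility class
#'
#' Given a complex-balanced steady state c, the jump process has the
#' equilibrium pi(X) propto prod_i c_i^X_i / X_i! restricted to the class
#' and normalized (the conditional product-of-Poissons form). Accumulation
#' is in log space. The result is independent of which complex-balanced c
#' is supplied.
#'
#' @param network an `eq_network` (used for dimension checking only).
#' @param conc strictly positive concentration vector, or the list returned
#'   by [complex_balanced_state()].
#' @param space an `eq_space` enumerating one compatibility class.
#' @return an `eq_distribution` on `space`.
#' @export
product_form_equilibrium <- function(network, conc, space) {
  if (is.list(conc)) conc <- conc$c
  if (any(conc <= 0)) stop("complex-balanced concentrations must be positive")
  if (length(conc) != ncol(space$states)) stop("concentration length mismatch")
  S <- space$states
  lw <- S %*% log(conc) - rowSums(lgamma(S + 1))
  lw <- drop(lw)
  equilibrium_distribution(exp(lw - logsumexp(lw)), space)
}
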