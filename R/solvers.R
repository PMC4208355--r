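# General-purpose equilibrium solvers: nullspace oracle, detailed-balance
# path formula with Horner normalization, circular-chain formula, Kirchhoff's
# spanning-tree method, and the one-vertex gluing rule.

#' Construct an equilibrium distribution object
#'
#' @param probs non-negative numeric vector summing to 1 (tolerance 1e-12
#'   after renormalization check).
#' @param space optional `eq_space` the distribution lives on.
#' @return an object of class `"eq_distribution"`.
#' @export
equilibrium_distribution <- function(probs, space = NULL) {
  if (any(!is.finite(probs)) || any(probs < -1e-14))
    stop("probabilities must be finite and non-negative")
  probs <- pmax(probs, 0)
  s <- sum(probs)
  if (s <= 0) stop("distribution has zero total mass")
  if (abs(s - 1) > 1e-12) probs <- probs / s
  if (!is.null(space) && length(probs) != n_states(space))
    stop("distribution length must match the state space")
  structure(list(probs = probs, space = space), class = "eq_distribution")
}

#' @export
print.eq_distribution <- function(x, ...) {
  cat(sprintf("Equilibrium distribution over %d states\n", length(x$probs)))
  invisible(x)
}

#' Brute-force nullspace equilibrium (the oracle)
#'
#' Identifies the closed communicating classes of the generator's support
#' graph (strongly connected components with no outgoing transition) and
#' solves, for each, the bordered linear system obtained by replacing one
#' balance equation with the normalization constraint. Falls back to a dense
#' SVD when the bordered system is singular; raises an error if the
#' nullspace within a class is numerically more than one-dimensional.
#'
#' Every analytic solver in the package is validated against this function.
#'
#' @param Q generator matrix (column convention, sparse or dense).
#' @param space optional `eq_space` attached to the result(s).
#' @return list of `eq_distribution`, one per closed communicating class;
#'   states outside a class get probability zero in its distribution.
#' @export
equilibrium_nullspace <- function(Q, space = NULL) {
  if (!inherits(Q, "Matrix")) Q <- Matrix::Matrix(Q, sparse = TRUE)
  Q <- as(Q, "generalMatrix")
  N <- nrow(Q)
  Tm <- as(as(Q, "TsparseMatrix"), "generalMatrix")
  keep <- Tm@i != Tm@j & Tm@x != 0
  # directed support edges from -> to (Q[to, from] > 0)
  from <- Tm@j[keep] + 1L; to <- Tm@i[keep] + 1L
  g <- igraph::make_empty_graph(N, directed = TRUE)
  if (length(from))
    g <- igraph::add_edges(g, as.vector(rbind(from, to)))
  comp <- igraph::components(g, mode = "strong")
  closed <- closed_classes(Q, comp)
  if (length(closed) == 0L) stop("no closed communicating class found")
  lapply(closed, function(cls) {
    pi_cls <- solve_class(Q[cls, cls, drop = FALSE])
    probs <- numeric(N)
    probs[cls] <- pi_cls
    equilibrium_distribution(probs, space)
  })
}

closed_classes <- function(Q, comp) {
  out <- list()
  for (k in seq_len(comp$no)) {
    cls <- which(comp$membership == k)
    outside <- setdiff(seq_len(nrow(Q)), cls)
    leak <- if (length(outside))
      sum(abs(Q[outside, cls, drop = FALSE])) else 0
    if (leak == 0) out[[length(out) + 1L]] <- cls
  }
  out
}

solve_class <- function(Qc) {
  n <- nrow(Qc)
  if (n == 1L) return(1)
  M <- as.matrix(Qc)
  M[1, ] <- 1  # replace one balance row by normalization
  rhs <- c(1, rep(0, n - 1))
  pi_hat <- tryCatch(solve(M, rhs), error = function(e) NULL)
  if (is.null(pi_hat) || any(!is.finite(pi_hat)) || any(pi_hat < -1e-8)) {
    sv <- svd(as.matrix(Qc))
    if (n >= 2 && sv$d[n - 1] < 1e-10 * max(sv$d, 1))
      stop(sprintf(
        "ill-conditioned generator: nullspace dimension > 1 within a class (sigma_{n-1} = %.3e)",
        sv$d[n - 1]))
    v <- sv$v[, n]
    if (sum(v) < 0) v <- -v
    pi_hat <- v / sum(v)
  }
  pmax(pi_hat, 0) / sum(pmax(pi_hat, 0))
}

#' Birth-death path rates container
#'
#' Rates for a finite path over states 0..N: `p[i]` is the forward rate
#' i-1 -> i is indexed as p\[i\] = p_{i-1} in the 0-based convention, i.e.
#' `p` has length N holding p_0..p_{N-1}, and `q` has length N holding
#' q_1..q_N. All rates must be strictly positive (reducible chains belong
#' to the nullspace oracle).
#'
#' @param p forward rates p_0..p_{N-1}.
#' @param q backward rates q_1..q_N.
#' @return object of class `"eq_path_rates"`.
#' @export
path_rates <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (length(p) > 0 && (any(p <= 0) || any(q <= 0)))
    stop("path rates must be strictly positive")
  structure(list(p = as.numeric(p), q = as.numeric(q)), class = "eq_path_rates")
}

#' Equilibrium of a finite birth-death path
#'
#' Detailed balance q_{i+1} pi_{i+1} = p_i pi_i gives
#' pi_i = pi_0 prod_{k<i} p_k / q_{k+1}; the normalizing constant is
#' evaluated with the Horner-style nested sum
#' 1/pi_0 = 1 + r_1 (1 + r_2 (1 + ... )), r_i = p_{i-1}/q_i, accumulated
#' right-to-left, which is stable for long paths. The products are carried
#' in log space.
#'
#' @param rates an `eq_path_rates` (or list with elements `p`, `q`).
#' @return an `eq_distribution` over states 0..N.
#' @export
equilibrium_path <- function(rates) {
  p <- rates$p; q <- rates$q
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (length(p) == 0L) return(equilibrium_distribution(1))
  if (any(p <= 0) || any(q <= 0)) stop("path rates must be strictly positive")
  r <- p / q                       # r_i = p_{i-1}/q_i
  # Horner nested sum, right to left: 1/pi0 = 1 + r_1(1 + r_2(1 + ...))
  acc <- 1
  for (i in rev(seq_along(r))) acc <- 1 + r[i] * acc
  lw <- c(0, cumsum(log(r)))       # log unnormalized weights
  if (is.finite(acc) && acc < 1e300 && max(lw) < 700) {
    w <- exp(lw) / acc
  } else {
    # overflow guard: normalize in log space instead
    w <- exp(lw - logsumexp(lw))
  }
  equilibrium_distribution(w)
}

#' Detailed-balance residual
#'
#' Maximum over ordered state pairs of |Q\[y,x\] pi_x - Q\[x,y\] pi_y|: zero
#' (to tolerance) exactly when the distribution is reversible for Q. Path
#' (tree-like) equilibria satisfy this by construction; equilibria on
#' cycles generally do not.
#'
#' @param Q generator matrix.
#' @param dist an `eq_distribution` (or bare probability vector).
#' @return maximum absolute pairwise flux imbalance.
#' @export
detailed_balance_residual <- function(Q, dist) {
  probs <- if (inherits(dist, "eq_distribution")) dist$probs else dist
  if (length(probs) != nrow(Q)) stop("distribution length must match Q")
  Qm <- as.matrix(Q)
  diag(Qm) <- 0
  F <- Qm %*% diag(probs)   # F[y,x] = rate(x->y) * pi_x
  max(abs(F - t(F)))
}

#' Equilibrium of a circular chain (cycle formula)
#'
#' States 1..N are arranged on a circle; `p[i]` is the clockwise rate
#' i -> i+1 and `q[i]` the counter-clockwise rate i -> i-1, indices mod N
#' (p_i for i > N is read as p_{i-N}). The stationary weight of state i is
#' the spanning-tree sum of the cycle: removing each edge in turn leaves a
#' path, and the product of the rates directed toward i along that path is
#' accumulated. Products are carried in log space when rates are extreme.
#'
#' @param p clockwise rates, length N >= 3.
#' @param q counter-clockwise rates, length N.
#' @return an `eq_distribution` over states 1..N.
#' @export
equilibrium_cycle <- function(p, q) {
  N <- length(p)
  if (length(q) != N) stop("p and q must have equal length")
  if (N < 3) stop("a cycle needs at least 3 states")
  if (any(p <= 0) || any(q <= 0)) stop("cycle rates must be strictly positive")
  use_log <- any(c(p, q) > 1e8) || any(c(p, q) < 1e-8)
  # edge e connects e and e+1 (mod N); removing it leaves the path
  # e+1, e+2, ..., e+N (= e). Directed toward state i the weight is
  # prod of p over edges strictly "before" i and q over edges after i.
  idx <- function(k) ((k - 1) %% N) + 1
  lw <- matrix(0, N, N)  # lw[i, e]: log weight of tree (cycle minus edge e) rooted at i
  for (e in seq_len(N)) {
    # path vertices in order v_0 = e+1, ..., v_{N-1} = e
    v <- idx(e + seq_len(N))
    for (ipos in seq_len(N)) {
      i <- v[ipos]
      s <- 0
      if (ipos > 1) for (k in seq_len(ipos - 1)) s <- s + log(p[v[k]])
      if (ipos < N) for (k in seq(ipos, N - 1)) s <- s + log(q[v[k + 1]])
      lw[i, e] <- s
    }
  }
  lse <- apply(lw, 1, logsumexp)
  w <- exp(lse - max(lse))
  equilibrium_distribution(w / sum(w))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Equilibrium by Kirchhoff's theorem (Markov chain tree theorem)
#'
#' The stationary weight of state i is proportional to the sum, over all
#' spanning trees of the undirected support graph, of the product of the
#' transition intensities on the tree's edges directed toward i. Zero
#' intensities contribute zero products. Enumeration is over (n-1)-subsets
#' of the undirected support edges, guarded to at most 12 states or 1e5
#' candidate subsets; products are evaluated in log space when intensities
#' are extreme.
#'
#' @param Q generator (column convention).
#' @param space optional `eq_space`.
#' @return an `eq_distribution`; errors if the support graph is
#'   disconnected (apply per component instead) or too large.
#' @export
equilibrium_kirchhoff <- function(Q, space = NULL) {
  Qm <- as.matrix(Q)
  n <- nrow(Qm)
  diag(Qm) <- 0
  und <- (Qm > 0) | (t(Qm) > 0)
  edges <- which(und & upper.tri(und), arr.ind = TRUE)
  ne <- nrow(edges)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (ne > 0) g <- igraph::add_edges(g, as.vector(t(edges)))
  if (n > 1 && !igraph::is_connected(g))
    stop("support graph is disconnected: apply Kirchhoff per component")
  if (n > 12 || choose(ne, n - 1) > 1e5)
    stop("too large for spanning-tree enumeration (guard: <= 12 states / 1e5 trees)")
  if (n == 1) return(equilibrium_distribution(1, space))
  use_log <- any(Qm[Qm > 0] > 1e8) || any(Qm[Qm > 0] < 1e-8)
  combs <- utils::combn(ne, n - 1)
  lw <- rep(-Inf, n); w <- numeric(n)
  for (cidx in seq_len(ncol(combs))) {
    sel <- combs[, cidx]
    el <- edges[sel, , drop = FALSE]
    tg <- igraph::make_empty_graph(n, directed = FALSE)
    tg <- igraph::add_edges(tg, as.vector(t(el)))
    if (!igraph::is_connected(tg)) next  # n-1 edges + connected => tree
    # orient every tree edge toward each root i and accumulate products
    for (i in seq_len(n)) {
      parent <- as.numeric(igraph::bfs(tg, root = i, father = TRUE)$father)
      lp <- 0
      ok <- TRUE
      for (v in seq_len(n)[-i]) {
        rate <- Qm[parent[v], v]  # transition v -> parent(v), toward root
        if (rate <= 0) { ok <- FALSE; break }
        lp <- lp + log(rate)
      }
      if (!ok) next
      if (use_log) lw[i] <- logsumexp(c(lw[i], lp)) else w[i] <- w[i] + exp(lp)
    }
  }
  if (use_log) {
    w <- exp(lw - max(lw))
  }
  if (sum(w) <= 0) stop("all spanning-tree products vanished")
  equilibrium_distribution(w / sum(w), space)
}

#' Glue two equilibria at one vertex
#'
#' Two Markov processes with known equilibria `pi1` (states 1..r) and `pi2`
#' (states 1..s) are joined by identifying state r of the first with state 1
#' of the second, keeping all transition rates. The glued process has
#' equilibrium proportional to: pi1_i * pi2_1 for the states of the first
#' chain (including the glue vertex) and pi1_r * pi2_j for j >= 2, states of
#' the second chain re-indexed by +r-1.
#'
#' @param pi1,pi2 `eq_distribution`s (or bare probability vectors).
#' @return an `eq_distribution` over r + s - 1 states.
#' @export
glue_equilibria <- function(pi1, pi2) {
  w1 <- if (inherits(pi1, "eq_distribution")) pi1$probs else pi1
  w2 <- if (inherits(pi2, "eq_distribution")) pi2$probs else pi2
  r <- length(w1); s <- length(w2)
  if (r < 1 || s < 1) stop("both distributions must be non-empty")
  w <- c(w1 * w2[1], w1[r] * w2[-1])
  equilibrium_distribution(w / sum(w))
}

#' Total variation distance between two distributions
#' @param a,b `eq_distribution`s or probability vectors of equal length.
#' @return 0.5 * sum |a - b|.
#' @export
total_variation <- function(a, b) {
  pa <- if (inherits(a, "eq_distribution")) a$probs else a
  pb <- if (inherits(b, "eq_distribution")) b$probs else b
  if (length(pa) != length(pb)) stop("length mismatch")
  0.5 * sum(abs(pa - pb))
}
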