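# Plain-text reaction file format, distribution serialization, and the
# seeded fixture generator.
#
# Format, one reaction per line:
#   2 M + 0 D -> 1 D ; k=1e3
# Integer coefficients are optional (default 1); `0` or an empty side is the
# empty complex; `; k=<float>` is mandatory; `#` begins a comment; species
# are declared implicitly. Reversible shorthand
#   A <-> B ; kf=1 ; kr=2
# expands to two reactions. The initial state is a companion line
#   init: M=100 D=0

parse_side <- function(txt, lineno) {
  txt <- trimws(txt)
  terms <- list()
  if (txt == "" || txt == "0") return(terms)
  for (piece in trimws(strsplit(txt, "+", fixed = TRUE)[[1]])) {
    if (piece == "" || piece == "0") next
    m <- regmatches(piece, regexec("^([0-9]+)?\\s*([A-Za-z_][A-Za-z0-9_*']*)$",
                                   piece))[[1]]
    if (length(m) == 0)
      stop(sprintf("parse error at line %d: malformed term '%s'", lineno, piece))
    coef <- if (m[2] == "") 1L else as.integer(m[2])
    terms[[length(terms) + 1L]] <- list(species = m[3], coef = coef)
  }
  terms
}

parse_rate <- function(txt, key, lineno) {
  m <- regmatches(txt, regexec(paste0("\\b", key, "\\s*=\\s*([-+0-9.eE]+)"),
                               txt))[[1]]
  if (length(m) == 0)
    stop(sprintf("parse error at line %d: missing rate '%s='", lineno, key))
  v <- suppressWarnings(as.numeric(m[2]))
  if (is.na(v)) stop(sprintf("parse error at line %d: bad rate value", lineno))
  if (v <= 0) stop(sprintf("domain error at line %d: rate must be positive", lineno))
  v
}

#' Parse a plain-text reaction network
#'
#' @param text character vector of lines, or a single string with newlines,
#'   or a file path via `file`.
#' @param file optional path to read instead of `text`.
#' @return list with `network` (an `eq_network`) and `init` (named initial
#'   state vector, NULL if no `init:` line).
#' @export
parse_network <- function(text = NULL, file = NULL) {
  if (!is.null(file)) text <- readLines(file, warn = FALSE)
  if (length(text) == 1L && grepl("\n", text)) text <- strsplit(text, "\n")[[1]]
  raw <- list()   # reactant/product term lists + rates, in order
  init <- NULL
  for (lineno in seq_along(text)) {
    line <- sub("#.*$", "", text[lineno])
    line <- trimws(line)
    if (line == "") next
    if (grepl("^init:", line)) {
      body <- trimws(sub("^init:", "", line))
      init <- list()
      for (kv in strsplit(body, "\\s+")[[1]]) {
        p <- strsplit(kv, "=", fixed = TRUE)[[1]]
        if (length(p) != 2)
          stop(sprintf("parse error at line %d: bad init entry '%s'", lineno, kv))
        init[[p[1]]] <- as.integer(p[2])
      }
      next
    }
    if (grepl("<->", line, fixed = TRUE)) {
      parts <- strsplit(line, ";")[[1]]
      sides <- strsplit(parts[1], "<->", fixed = TRUE)[[1]]
      if (length(sides) != 2)
        stop(sprintf("parse error at line %d: malformed reversible reaction", lineno))
      kf <- parse_rate(line, "kf", lineno)
      kr <- parse_rate(line, "kr", lineno)
      lhs <- parse_side(sides[1], lineno); rhs <- parse_side(sides[2], lineno)
      raw[[length(raw) + 1L]] <- list(lhs = lhs, rhs = rhs, rate = kf)
      raw[[length(raw) + 1L]] <- list(lhs = rhs, rhs = lhs, rate = kr)
    } else if (grepl("->", line, fixed = TRUE)) {
      parts <- strsplit(line, ";")[[1]]
      sides <- strsplit(parts[1], "->", fixed = TRUE)[[1]]
      if (length(sides) != 2)
        stop(sprintf("parse error at line %d: malformed reaction", lineno))
      k <- parse_rate(line, "k", lineno)
      raw[[length(raw) + 1L]] <- list(lhs = parse_side(sides[1], lineno),
                                      rhs = parse_side(sides[2], lineno),
                                      rate = k)
    } else {
      stop(sprintf("parse error at line %d: no '->' found", lineno))
    }
  }
  if (length(raw) == 0) stop("parse error: no reactions found")
  species <- unique(unlist(lapply(raw, function(r)
    vapply(c(r$lhs, r$rhs), `[[`, character(1), "species"))))
  to_vec <- function(terms) {
    v <- integer(length(species))
    for (t in terms) v[match(t$species, species)] <- v[match(t$species, species)] + t$coef
    v
  }
  reactions <- lapply(raw, function(r)
    reaction(to_vec(r$lhs), to_vec(r$rhs), r$rate))
  net <- reaction_network(species, reactions)
  X0 <- NULL
  if (!is.null(init)) {
    X0 <- setNames(integer(length(species)), species)
    for (nm in names(init)) {
      if (!nm %in% species)
        stop("parse error: init references unknown species ", nm)
      X0[nm] <- init[[nm]]
    }
  }
  list(network = net, init = X0)
}

#' Serialize a reaction network to the plain-text format
#'
#' Canonical output: one reaction per line in network order, full-precision
#' rates, and an `init:` line when an initial state is supplied.
#' `parse_network(write_network(net))` round-trips.
#'
#' @param network an `eq_network`.
#' @param init optional initial state.
#' @return character vector of lines.
#' @export
write_network <- function(network, init = NULL) {
  side <- function(coefs) {
    nz <- which(coefs > 0L)
    if (!length(nz)) return("0")
    paste(vapply(nz, function(i)
      if (coefs[i] == 1L) network$species[i]
      else paste(coefs[i], network$species[i]), character(1)), collapse = " + ")
  }
  lines <- vapply(network$reactions, function(r)
    sprintf("%s -> %s ; k=%s", side(r$reactant), side(r$product),
            format(r$rate, digits = 17)), character(1))
  if (!is.null(init))
    lines <- c(lines, paste("init:", paste(network$species, init,
                                           sep = "=", collapse = " ")))
  lines
}

#' Serialize an equilibrium distribution
#'
#' TSV: one column per species (state counts) plus `probability`
#' (17 significant digits, lossless float round-trip); rows in enumeration
#' order. JSON mirrors the same content with state arrays.
#'
#' @param dist an `eq_distribution` with an attached state space.
#' @param format `"tsv"` or `"json"`.
#' @return character scalar (the serialized text).
#' @export
write_distribution <- function(dist, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (is.null(dist$space) || n_states(dist$space) == 0)
    stop("distribution has no state space attached")
  S <- dist$space$states
  if (format == "tsv") {
    hdr <- paste(c(colnames(S), "probability"), collapse = "\t")
    rows <- vapply(seq_len(nrow(S)), function(i)
      paste(c(S[i, ], format(dist$probs[i], digits = 17, scientific = TRUE)),
            collapse = "\t"), character(1))
    paste(c(hdr, rows), collapse = "\n")
  } else {
    jsonlite::toJSON(list(
      species = colnames(S),
      states = unname(apply(S, 1, as.integer, simplify = FALSE)),
      probability = dist$probs), digits = NA, auto_unbox = FALSE)
  }
}

#' Read back a TSV-serialized distribution
#' @param text TSV text produced by [write_distribution()].
#' @return an `eq_distribution` with its state space.
#' @export
read_distribution <- function(text) {
  con <- textConnection(text)
  on.exit(close(con))
  df <- utils::read.delim(con, check.names = FALSE)
  S <- as.matrix(df[, -ncol(df), drop = FALSE])
  storage.mode(S) <- "integer"
  equilibrium_distribution(df[[ncol(df)]], new_space(S))
}

#' Seeded random fixture generator
#'
#' Deterministic test networks with rates drawn log-uniformly from
#' `rate_range` under `seed`:
#' * `"path"`: a token hopping along N+1 species (birth-death path with
#'   arbitrary per-state rates);
#' * `"cycle"`: a token on an N-species ring;
#' * `"glued"`: a path whose last state opens into a ring (one-vertex glue);
#' * `"hypercube"`: N-site independent TF binding (compounded);
#' * `"ladder"`: the dimer-TF network with T monomers;
#' * `"random-motif"`: one of the above, chosen by the seed.
#'
#' @param topology fixture family.
#' @param size N (path/cycle/hypercube sites) or T (ladder).
#' @param seed integer seed; identical specs give identical fixtures.
#' @param rate_range log-uniform bounds for the rate constants.
#' @return list with `network`, `init`, `space`, and the drawn `rates`.
#' @export
generate_fixture <- function(topology = c("path", "cycle", "glued",
                                          "hypercube", "ladder",
                                          "random-motif"),
                             size, seed, rate_range = c(0.1, 10)) {
  topology <- match.arg(topology)
  set.seed(seed)
  draw <- function(k) exp(runif(k, log(rate_range[1]), log(rate_range[2])))
  if (topology == "random-motif") {
    topology <- sample(c("path", "cycle", "glued", "hypercube", "ladder"), 1)
  }
  token_chain <- function(n_sp, edges, rates) {
    # edges: 2-column matrix of (from, to) site indices; one token
    rxn <- lapply(seq_len(nrow(edges)), function(e) {
      a <- integer(n_sp); b <- integer(n_sp)
      a[edges[e, 1]] <- 1L; b[edges[e, 2]] <- 1L
      reaction(a, b, rates[e])
    })
    reaction_network(paste0("P", seq_len(n_sp)), rxn)
  }
  if (topology == "path") {
    N <- size
    edges <- rbind(cbind(1:N, 2:(N + 1)), cbind(2:(N + 1), 1:N))
    net <- token_chain(N + 1, edges, draw(2 * N))
    init <- c(1L, integer(N))
  } else if (topology == "cycle") {
    N <- size
    stopifnot(N >= 3)
    fwd <- cbind(1:N, c(2:N, 1))
    edges <- rbind(fwd, fwd[, 2:1])
    net <- token_chain(N, edges, draw(2 * N))
    init <- c(1L, integer(N - 1))
  } else if (topology == "glued") {
    # path of `size` edges, then a 4-ring glued at the path's far end
    Np <- size
    n_sp <- Np + 4  # path sites 1..Np+1, ring adds 3 more
    ring <- c(Np + 1, Np + 2, Np + 4, Np + 3)
    fwd <- rbind(cbind(1:Np, 2:(Np + 1)),
                 cbind(ring, c(ring[-1], ring[1])))
    edges <- rbind(fwd, fwd[, 2:1])
    net <- token_chain(n_sp, edges, draw(nrow(edges)))
    init <- c(1L, integer(n_sp - 1))
  } else if (topology == "hypercube") {
    N <- size
    k <- draw(2)
    res <- hypercube_compounded(N, 2L * N, k[1], k[2])
    return(list(network = res$network, init = res$space$states[1, ],
                space = res$space, rates = k, topology = topology))
  } else {  # ladder
    T_mono <- size
    k <- draw(4)
    lad <- dimer_tf_network(T_mono, k[1], k[2], k[3], k[4])
    return(list(network = lad$network, init = lad$space$states[1, ],
                space = lad$space, rates = k, topology = topology))
  }
  space <- enumerate_compatibility_class(net, init)
  list(network = net, init = init, space = space,
       rates = vapply(net$reactions, `[[`, numeric(1), "rate"),
       topology = topology)
}
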