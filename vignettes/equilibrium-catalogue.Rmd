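---
title: "A catalogue of analytic equilibria for biochemical reaction motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A catalogue of analytic equilibria for biochemical reaction motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqmotif)
```

## The model

A reaction network over species $S_1,\dots,S_n$ is a list of channels
$\alpha_j \to \beta_j$ with rate constants $\kappa_j$ and state changes
$\nu_j = \beta_j - \alpha_j$. The stochastic model is the continuous-time
Markov jump process on non-negative integer count vectors $X$ in which
channel $j$ fires at the stochastic mass-action propensity: $\kappa$
(zeroth order), $\kappa X_i$ (first order), $\kappa X_i X_k$
(heterogeneous bimolecular) or $\kappa X_i(X_i-1)$ (homogeneous
bimolecular). Two conventions deserve emphasis because they differ across
the literature:

* **No factor 1/2 on homogeneous bimolecular channels.** A dimerization
  $2M \to D$ with $M$ monomers fires at $\kappa M(M-1)$, full stop. Users
  whose constants follow the $\tfrac12 \kappa M(M-1)$ convention must fold
  the 1/2 into $\kappa$.
* **Column generator.** The master equation is written $dP/dt = QP$ with
  $Q[y,x]$ the intensity of the jump $x \to y$ and columns summing to zero,
  so an equilibrium distribution is a *right* nullvector of $Q$. Transposed
  (row-generator) conventions are equally common elsewhere.

Left nullvectors $w$ of $\nu$ are conserved quantities; they partition the
state space into stoichiometric compatibility classes, enumerated here
breadth-first from an initial state (neighbours in reaction order, forward
displacement before backward), which fixes a deterministic state order for
all tests and serializations. Rate constants are taken as already
stochastic: no volume conversion is applied.

## Solvers and their hierarchy

`equilibrium_nullspace()` is the package's oracle: it finds the closed
communicating classes on the directed support graph (strongly connected
components with no outgoing rate) and solves each class's balance
equations with one row replaced by the normalization constraint, falling
back to an SVD when the bordered system is singular and erroring when the
within-class nullspace is numerically more than one-dimensional. It is
deliberately free of structural shortcuts so that every analytic solver can
be validated against it; the test suite does exactly that, over seeded
log-uniform rate draws, at $10^{-10}$ or tighter.

The analytic layer exploits structure:

* **Paths.** Detailed balance $q_{i+1}\pi_{i+1} = p_i\pi_i$ gives
  $\pi_i = \pi_0 \prod_{k<i} p_k/q_{k+1}$. The normalizing sum is evaluated
  with the Horner-style nested form $1 + r_1(1 + r_2(1+\dots))$ from the
  right, and the weights in log space; a 300-state path with rate ratios of
  $10^8$ per step normalizes without overflow (tested).
* **Cycles.** On a ring detailed balance generally fails (probability flux
  circulates), but the stationary weights are the spanning-tree sums of the
  cycle: dropping each edge in turn leaves a path whose rates, directed
  toward the target state, are multiplied and accumulated. The same
  Markov-chain-tree principle is implemented in general in
  `equilibrium_kirchhoff()`, which enumerates $(n-1)$-edge subsets of the
  undirected support graph, keeps the spanning trees, and guards itself to
  at most 12 states or $10^5$ candidate subsets. (The guard, not
  contraction–deletion recursion, is what keeps this honest: tree
  enumeration is exponential and the package prefers a hard refusal over a
  silent stall.) Products switch to log space when intensities leave
  $[10^{-8}, 10^8]$.
* **Gluing.** If two chains with equilibria $\pi^1$ (states $1..r$) and
  $\pi^2$ (states $1..s$) are joined by identifying state $r$ with state 1,
  keeping all rates, the glued equilibrium is proportional to
  $\pi^1_i \pi^2_1$ on the first chain and $\pi^1_r \pi^2_j$ on the second.
  Gluing happens at one vertex at a time; cycles enter whole.

## The motif catalogue

Each constructor returns the explicit network, its enumerated class, the
closed form, and the parameter map, so the closed form can always be
replayed against the oracle or an SSA run. The catalogue covers the
birth–death process (Poisson), isomerization (binomial — also a coarse
Goldbeter–Koshland switch with effective rates $\kappa'_+E_1$,
$\kappa'_-E_2$), TF binding to $N$ gene copies, dimerization (even/odd
total), the two-state gene (Bernoulli; its occupancy is a Hill function of
the TF count with coefficient 1), ordered two-site binding (three-state
path; a `helpers = H` flag rescales the first binding propensity, treating
the helper-recruitment variant as the same path rather than a new motif),
two-site independent binding (four-state cycle), compounded hypercube
occupancy, and the two glued three-TFBS models.

Two catalogue decisions were genuinely open:

* For the independent two-site model the package ships the closed form only
  under the symmetric-rate assumption (the same constants for both sites),
  where the Kolmogorov criterion holds and the weights are
  $(1, a, a, ab)$ with $a = \kappa_0 T/\kappa_{-1}$,
  $b = \kappa_1(T-1)/\kappa_{-2}$. The general non-symmetric cycle is
  reachable through `equilibrium_cycle()`; hard-coding a "closed form" for
  it would just re-implement that function.
* `tf_binding()` stores the total TF count $T$ and applies $(T-i)$ free TFs
  inside the rates; when $N > T$ the roles of gene and TF are swapped with
  a message rather than an error, since the distribution is the same chain
  read from the other end.

## Chemical reaction network theory

`crnt_report()` computes complexes, linkage classes (components of the
complex graph), weak reversibility (every component strongly connected,
checked as: weak and strong component counts coincide), the stoichiometric
subspace dimension, and the deficiency. For weakly reversible
deficiency-zero networks a complex-balanced steady state $c > 0$ of the
*deterministic* model exists for any rate constants;
`complex_balanced_state()` finds one by BFGS in log-concentration space
(positivity structural, 10 seeded multistarts, relative residual
$< 10^{-10}$). Deliberate asymmetry: the deterministic balance equations
use monomials $c^{\alpha}$ while the stochastic propensities use falling
factorials — that mismatch is exactly what the product-form correspondence
requires, not a bug. The stochastic equilibrium is then
$\pi(X) \propto \prod_i c_i^{X_i}/X_i!$ restricted to the compatibility
class (log-space accumulation); the conditional distribution is invariant
to which complex-balanced $c$ is chosen, a property the tests assert by
rescaling $c$ along the balance manifold. Conditioning destroys
independence: isomerization restricted to $X_1+X_2=N$ is the binomial law,
which the catalogue reproduces by a different route. Kinetics more general
than mass action are not supported in this module.

## The dimer-TF ladder

The flagship model couples $2M \rightleftharpoons D$
($\kappa_1, \kappa_{-1}$) with $G + D \rightleftharpoons G^*$
($\kappa_b, \kappa_u$), one gene copy, $T$ total monomers
($T = M + 2D + 2G^*$, $G + G^* = 1$). The state is (total dimers, gene
state) on a ladder of $2\lfloor T/2\rfloor + 1$ states — one side one state
longer. Generating-function techniques stall here (the finite dimer pool
truncates the PDE system), so the exact route is the product form:
with $c_M = 1$, $c_D = \kappa_1/\kappa_{-1}$,
$c_{G^*} = \kappa_b c_D/\kappa_u$, the gene-free and gene-bound marginal
sums are evaluated in log space and combined, giving
$\Pr_T(G^*=0)$ exactly for any $T$ (tested against the oracle to
$10^{-10}$ for $T$ up to 40, and exercised at $T = 800$).

For the large-$T$ asymptotic the two marginal sums are coefficient
extractions from $e^{c_D z^2 + z}$: $S_0(T) = [z^T]$, and the gene-bound
sum is $S_0(T-2)$ up to the factor $c_{G^*}$. The saddle point $r$ solves
$2 c_D r^2 + r = T$ — precisely the deterministic monomer count $m^*$, so
$c_{G^*} S_0(T-2)/S_0(T) \approx \kappa_b (T - m^*) / (2\kappa_u)$ and the
odds of the gene being free are $2\kappa_u / (\kappa_b (T - m^*))$. Since
$m^* = O(\sqrt{T})$ with a coefficient depending on
$\kappa_1/\kappa_{-1}$, and the saddle-point error terms are of the same
order, the method cannot resolve the dimerization constants; dropping
$m^*$ and the odds-to-probability correction leaves

$$\Pr_T(G^*=0) \;\approx\; \frac{2\kappa_u}{\kappa_b T},$$

a function of $\kappa_b$, $\kappa_u$, $T$ only. As a truncated asymptotic
series it exceeds 1 when $T < 2\kappa_u/\kappa_b$; the implementation clips
to $[0,1]$ with a warning rather than erroring, since raising $T$ always
restores validity. The tests verify that its relative error against the
exact marginal falls monotonically along $T = 50, 100, 200, 400$, that the
exact marginal's dependence on $\kappa_1, \kappa_{-1}$ vanishes as $T$
grows, and that the formula tracks the single-monomer law with $T/2$ TFs.
The deterministic dimer count is closed-form:
$d^* = (T - m^*)/2$ with
$m^* = (-\kappa_{-1} + \sqrt{\kappa_{-1}^2 + 8\kappa_1\kappa_{-1}T})/(4\kappa_1)$,
so $T/2 - d^*$ grows like $\sqrt{T}$ (ratio $\approx 2$ between $4T$ and
$T$, tested).

## QSSA averaging and the slow-scale SSA

Under time-scale separation the fast subsystem is assumed at its
conditional equilibrium given the slow variables, and each slow propensity
is replaced by its expectation under that equilibrium (law of total
expectation): for a gene switching fast between free and bound forms with
transcription rates $a_u$, $a_b$, the effective mRNA birth rate is
$a_u \Pr(\text{free}) + a_b \Pr(\text{bound})$ — whether the TF activates
or represses is carried entirely by the relative magnitudes of $a_u, a_b$.
`slow_scale_ssa()` simulates only the slow variables, memoizing the
averaged rates per slow-state value (the fast equilibrium depends on the
slow state only through conserved totals). The package does **not** verify
the separation assumption itself — the user asserts it; with weakly
separated scales the reduction is simply wrong, and no warning will fire.

Randomness: the SSA (direct method, compiled) and the slow-scale SSA draw
from R's RNG, so `set.seed`/the `seed` argument fixes trajectories exactly;
this replaces a counter-based generator design that is idiomatic in other
ecosystems but redundant given R's stable, portable Mersenne–Twister.
Monte Carlo error bands use batch means over 20 windows, the standard
estimator for autocorrelated occupancy averages.

## What the synthetic fixtures do and do not establish

`generate_fixture()` draws rates log-uniformly from $[0.1, 10]$ — about the
dynamic range over which all catalogued chains remain well-conditioned and
which spans weak-to-strong binding regimes — on path, cycle, glued,
hypercube and ladder topologies with single-token or motif-sized state
spaces. Green oracle-equivalence tests therefore establish *algebraic
correctness of the closed forms on their stated topologies*, not numerical
robustness at pathological rate ratios (covered only by the dedicated
overflow tests) and not model adequacy for any real regulatory system: the
fixtures emulate the structure of the catalogued motifs, not measured
kinetics, copy-number noise from slow processes, or diagonal (concerted)
transitions, which the ladder model explicitly lacks. SSA-based checks are
statistical: they run at seeded, reduced sample sizes and assert agreement
within three batch-means standard errors, so they bound gross errors, not
ulp-level bias.

## Numerical choices

* Bordered solve first, SVD fallback; ill-conditioning beyond one
  nullvector per class raises with a condition estimate.
* Log-space products throughout (paths, trees, product form) with
  `logsumexp` normalization; linear-space Horner kept when it cannot
  overflow.
* Reflecting truncation for infinite classes: outgoing rates at the
  boundary are removed so the truncated $Q$ stays a proper generator; the
  birth–death cutoff is the smallest Poisson-tail quantile with mass
  $\ge 1 - \varepsilon$, other infinite classes grow a count cap
  geometrically until the boundary shell holds $< \varepsilon$ mass.
* Duplicate reactions merge by summing $\kappa$; zero-rate channels in
  degenerate motifs (e.g. $\kappa_1 = 0$ in the sequential model) drop the
  channel but keep the unreachable state in the class, with probability 0.
* Exact integer arithmetic (fraction-free elimination) for conservation
  laws, so $w^\top\nu = 0$ holds exactly, not to tolerance.

## Known limitations

Beyond-bimolecular kinetics require explicit propensity rules and are
excluded from the CRNT module; the Kirchhoff solver refuses more than 12
states; gluing at two vertices simultaneously is out of scope; the dimer
asymptotic is leading-order only, so the occupancy-deficit series for the
dimer mechanism stops at $1/T$ while the other three mechanisms admit
arbitrary-order series (computed by exact polynomial series division of
their rational occupancy functions); and the CLI's `--method auto` selects
by CRNT structure (product form when deficiency zero and weakly
reversible, else nullspace) rather than by pattern-matching networks to
catalogue entries — closed forms are available through their constructors
and the `motif` subcommand instead.
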