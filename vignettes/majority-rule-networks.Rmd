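---
title: "Stochastic majority rules on Boolean gene regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic majority rules on Boolean gene regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnmr)
library(dplyr)
```

## The model

A threshold Boolean gene regulatory network is a signed directed graph: nodes
are genes, an edge $j \to i$ with sign $a_{ij} \in \{+1, -1\}$ is an
activation or an inhibition. Every node carries a value, and all nodes update
synchronously by a majority vote among their regulators. Writing $s_j \in
\{-1, +1\}$ for the value of node $j$ (spin form), the contribution sum of
node $i$ is

$$U_i(t) = \sum_{j \to i} a_{ij}\, s_j(t),$$

and the update sets $s_i(t+1) = +1$ when $U_i > 0$ and $-1$ when $U_i < 0$.
The interesting case is the tie, $U_i = 0$, where activations and
repressions cancel exactly. Instead of fixing an arbitrary convention, the
stochastic **majority rule (MR)** draws the next value at random: $+1$ with
probability $p_i$, $-1$ with probability $1 - p_i$. Every other update stays
deterministic, so the dynamics mixes deterministic and probabilistic nodes:
under the MR a node is deterministic exactly when its in-degree is odd (an
odd sum of $\pm 1$ terms is never zero).

Three variants alter the tie treatment or the value semantics:

* **IMR** (inertial): a tied node keeps its current value with probability
  $p_i$ (and flips with $1 - p_i$); $p_i = 1$ recovers the classic
  deterministic inertial rule. Realised here as a keep-probability, i.e. the
  probability of the high outcome depends on the current value.
* **NMR** (null): values are Boolean, $S_j \in \{0, 1\}$, so an absent
  regulator contributes nothing instead of voting against its usual effect.
  All nodes become probabilistic (the empty product of contributions at the
  all-zero configuration ties every node), and a node with only inhibitors
  can never be switched on.
* **INMR**: the Boolean representation with the inertial tie treatment; this
  is the stochastic version of the rule used by the classic budding-yeast
  cell-cycle model, which becomes that deterministic model at $p = 1$.

Spin and Boolean representations are linked by the componentwise bijection
$S = (s + 1)/2$; `convert_representation()` implements it and the state
indexing (`state_to_index()`) is the big-endian bit string with node 1 most
significant and the high value mapping to bit 1.

With at least one probabilistic node the dynamics is a finite Markov chain
on the $2^n$ configurations. The package builds the transition matrix
exactly — entry $x \to y$ is the product of per-node probabilities, and all
arithmetic is done in exact rational numbers whenever tie probabilities are
given as fractions (`"1/3"`). Attractors are the terminal strongly connected
components of the support digraph. Extending the textbook notion, a chain is
*absorbing* when every ergodic set is deterministic — a fixed point or a
deterministic cycle; it is *regular* when a single aperiodic ergodic set
covers the whole space. For absorbing chains the fundamental matrix
$N = (I - Q)^{-1}$ over the transient states gives expected visit counts and
absorption times; for regular chains the stationary vector $\pi$ gives the
mean return times $m_i = 1 / \pi_i$.

## Tunable parameters

* `tie_prob` — one tie probability per node, in $[0, 1]$, default `"1/2"`
  (dimensionless). Fraction strings keep every downstream quantity exact;
  plain numerics that match a small fraction (denominator up to 1024) are
  also treated exactly, anything else falls back to doubles.
* "Generic parameters" in the two-node atlas default to $p = 1/3$,
  $q = 2/3$: distinct rationals strictly inside $(0,1)$, so no structurally
  positive transition vanishes and the support digraph is
  parameter-independent. Extreme values (0 or 1) are a separate, explicit
  mode (`extreme_deterministic_map()`), and `support_digraph(generic =
  TRUE)` refuses them.
* `clamped` — input clamps; a clamped node is frozen and removed from the
  state space, so an 11-node network with one clamp yields a 1024-state
  chain.

## The two-node atlas

A *module* is one node with its incoming interactions. With both nodes
self-regulated and cross-regulated there are four modules per node (self
sign × cross sign) and sixteen composed models (`enumerate_two_node_models()`).
The row rotation `rho_rotate()` cycles the four module update tables.
The models split into two families by the location of their ties: *in
phase* models (both nodes tie in the same two configurations; two fully
probabilistic matrix rows, two deterministic ones, ten support transitions)
and *out of phase* models (one tied node per row; eight transitions).
`model_phase()` decides the family by the operational row pattern and
asserts it coincides with the structural criterion (equal products of self
and cross signs).

Isomorphism between models means equal matrices up to a renaming of the four
states and a bijective substitution of the parameters into
$\{p, 1-p, q, 1-q\}$. Matrix entries are bilinear in $(p, q)$, so exact
agreement at three generic rational points — $(1/3, 2/7)$, $(2/5, 3/7)$,
$(1/7, 5/11)$ — implies identity; `models_isomorphic()` searches the
$24 \times 8$ witnesses exhaustively and `atlas_classes()` takes the
transitive closure. The result is three in-phase and three out-of-phase
classes of sizes 2, 2 and 4, labelled by their structural signature
(IP1/OP1: two self-activations, IP2/OP2: two self-inhibitions, IP3/OP3:
self-asymmetric). The same engine classifies the IMR variants into exactly
the same partition. For the Boolean variants the row patterns above do not
apply, so `atlas_classes("NMR")` reports neutral `class<k>` labels from the
isomorphism partition alone.

Two findings are worth stating because they differ from a naive reading:

* Under the keep-probability IMR semantics adopted here (the only one whose
  $p = 1$ limit is the deterministic inertial rule), *every* module has one
  tie row where the IMR distribution differs from the MR one, so no
  composed model has an entrywise MR-identical IMR matrix. What does hold,
  and is tested, is that the IMR class structure equals the MR one, and the
  worked out-of-phase example behaves as documented: the two loop
  probabilities of the OP3 model are $1-p$ and $p$ under the MR but both
  $p$ under the IMR.
* The IP3 return-time ordering is pairwise: the mean return time to the
  source of each deterministic transition always exceeds the return time to
  its target. The global form ("targets have the smallest return times") is
  false — at $p = 1/5$, $q = 2/5$ a tied state beats a deterministic
  target.

The chain of any two-node model can also be realised as a random walk over
its four extreme deterministic maps (`random_map_sampler()`): at each step a
corner of the parameter square is drawn with the product probabilities
implied by independent per-node tie outcomes and its unique transition
applied. The induced one-step law equals the transition matrix exactly —
this is the package's bridge between the tie-probability picture and the
"random choice of logical functions" picture (at the extreme corners the
update rules are ordinary AND/OR gates, see `logic_corner_table()`).

## The yeast cell-cycle case study

`yeast_network()` ships the 11-node budding-yeast cell-cycle wiring in three
variants. The `original_with_selfloops` variant carries the five negative
self-loops that the classic deterministic model adds to the nodes lacking a
negative regulator (Cln3, Cln1/2, Swi5, Cdc20, Mcm1/SFF); because the MR
already lets an absent regulator vote, those loops can be discarded, giving
`mr_pruned`. The `revised` variant adds the two positive feedback edges
Cln1/2 → SBF and Clb5/6 → MBF.

A configuration is *steady* when its self-transition probability is
positive: every deterministic module must reproduce its value, and each tied
module contributes a factor $p_i$ or $1 - p_i$. `steady_configurations()`
scans the full diagonal; `deterministic_core_candidates()` +
`extend_core()` implement the staged search that first solves the
deterministic modules (and is cross-checked against the brute force in the
tests).

Two conventions matter and are worth making explicit:

* The staged core search that yields 2 satisfiable assignments out of 32
  runs on the *original* wiring with Cln3 exempted as a clamped input —
  there the five deterministic non-input modules are Cdc20, Clb5/6, Sic1,
  Clb1/2 and Mcm1/SFF. On the pruned wiring the deterministic set is
  different (Cln1/2, Swi5, Clb5/6, Sic1, Clb1/2) and six core assignments
  are satisfiable, so the two counts are *not* interchangeable.
* MR dynamics are symmetric under flipping every value together with
  $p \to 1-p$, so steady configurations come in mirror pairs whenever the
  input is free: on `mr_pruned` the scan finds exactly the biological G1
  state (only Cdh1 and Sic1 ON, self-probability
  $(1-p_{Cln3})(1-p_{MBF})(1-p_{SBF})$) and its global flip. The uniqueness
  statement — G1 is the *only* steady configuration — is conditional on the
  input value, and holds once Cln3 is clamped OFF. Both readings are
  computed and tested; uniqueness is never claimed for the free-input
  network.

G1 is steady but not absorbing: its tied modules (MBF, SBF, and Cln3 when
free) leave with positive probability. `suggest_stabilizing_edges()`
enumerates the single-edge additions that determinise a tied module with the
correct sign — a positive edge from a node low at G1 or a negative edge from
a node high at G1 — and recovers, among others, exactly the two
biologically motivated revision edges. After `apply_edits()` adds them and
the input is clamped OFF, G1 becomes absorbing and is the unique ergodic
set of the 1024-state chain; clamping the input ON yields the value-flipped
mirror (at tie probabilities 1/2). The deterministic INMR on the original
wiring has seven fixed points (G1 plus six others), reproduced by
`extreme_deterministic_map()` over all 2048 configurations.

```{r yeast}
net <- yeast_network("mr_pruned", clamp_input = "off")
steady_configurations(net)
suggest_stabilizing_edges(net, yeast_g1("spin")) |>
  filter(sign > 0)
```

## Numerical choices

* **Exact arithmetic.** Tie probabilities given as fractions propagate as
  exact integer numerator/denominator pairs held in doubles (safe far below
  $2^{53}$; an overflow or a non-representable value degrades gracefully to
  doubles and is flagged). Row sums, fundamental matrices and stationary
  vectors are exact in this mode; the rational linear solver is a dense
  Gauss–Jordan elimination, used only for small systems (two-node chains,
  transient blocks up to 64 states), with `Matrix`/`solve()` as the
  large-system fallback.
* **Deterministic-cycle absorption.** When ergodic sets include
  deterministic cycles, $Q$ is taken from the $k$-th matrix power ($k$ the
  lcm of the cycle periods) and the per-$k$-step visit counts are scaled by
  $k$; this convention is documented rather than canonical, and the
  simulator cross-checks cover the fixed-point case.
* **Aperiodicity** for the regular label is decided on the support digraph
  as the gcd of cycle lengths through a reference state (BFS levels).
* **Degenerate inputs.** In-degree-0 nodes have an empty contribution sum —
  a perpetual tie under MR/NMR — unless clamped. Clamps beat rules and
  never tie. Extreme tie probabilities turn ties deterministic and are
  excluded from "generic" analyses.

## The simulator and what a green test establishes

`sample_trajectory()` draws every tied node independently, in node order,
from one seeded RNG stream per call, so trajectories are bit-reproducible.
`estimate_return_times()` and `estimate_absorption()` report means with
standard errors and count horizon-censored runs separately. The test suite
compares these estimators against the exact analytics at three standard
errors with fixed seeds: such a test validates that the simulator and the
matrix construction implement the same chain, not that either matches a
biological system. The two-node atlas and the yeast model are exact,
enumerable objects — the synthetic element is only the choice of parameter
points, fixed as described above, and deliberately not tuned.

## Limitations

* Interaction weights other than one and non-zero thresholds are out of
  scope, as are asynchronous update schemes and multi-valued variables.
* The brute-force steady scan is bounded at 20 nodes; the staged search
  relies on the deterministic/probabilistic split and therefore applies to
  the spin rules only.
* Isomorphism witnesses are certified for two-node models; the general
  engine does not scale past the four-state space.
* Mixing times, spectral analysis and continuous-time embeddings are not
  computed.
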