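# grnmr

Stochastic majority-rule Boolean gene regulatory networks: exact Markov
chain analytics, the complete two-node model atlas, and steady-state
search with edge-addition repair, demonstrated on the budding-yeast
cell-cycle network.

## The problem

Threshold Boolean networks model gene regulation by a majority vote: a gene
turns ON when the signed contributions of its regulators sum positive
(activators count $+1$ when present, repressors $-1$) and OFF when the sum
is negative. The delicate case is the **tie**, where activations and
repressions cancel exactly. Rather than adopting an arbitrary convention,
the stochastic majority rule (MR) draws the next value at random — ON with
probability $p_i$, OFF with $1 - p_i$ — and leaves every other update
deterministic:

$$
s_i(t+1) =
\begin{cases}
+1 & \text{if } U_i(t) > 0,\\
-1 & \text{if } U_i(t) < 0,\\
+1 \text{ w.p. } p_i,\; -1 \text{ w.p. } 1 - p_i & \text{if } U_i(t) = 0,
\end{cases}
\qquad
U_i(t) = \sum_{j \to i} a_{ij}\, s_j(t).
$$

The resulting dynamics is a finite Markov chain on the $2^n$ configurations
that mixes deterministic nodes (odd in-degree) with probabilistic ones
(even in-degree). Three variants alter the tie treatment: inertial (IMR,
keep the current value with probability $p_i$), null (NMR, Boolean 0/1
values so absent regulators abstain), and their combination (INMR, the
stochastic version of the rule behind the classic yeast cell-cycle model).

The package is aimed at people studying logical models of regulatory
networks who want *exact* answers about the stochastic dynamics: which
configurations are attractors, how long the chain lingers before
absorption, what the mean return times are, and — the practical payoff —
which single regulatory edges would make a desired biological state
absorbing.

## What it computes

* **Exact chains** — `transition_model()` builds the $2^n \times 2^n$
  row-stochastic matrix in exact rational arithmetic (tie probabilities as
  fractions, e.g. `"1/3"`); `ergodic_sets()` finds attractors as terminal
  strongly connected components; `classify_chain()` labels chains absorbing
  (in the extended sense that allows deterministic cycles), regular, or
  mixed; `fundamental_matrix()`, `absorption_probabilities()` and
  `stationary_distribution()` deliver $N = (I-Q)^{-1}$, $B = NR$, $\pi$ and
  the mean return times $m_i = 1/\pi_i$.
* **The two-node atlas** — all 16 models composed from two self- and
  cross-regulated modules, the in-phase / out-of-phase partition, the
  isomorphism classification into six classes of sizes (2, 2, 4) per phase
  family, the AND/OR logic realised at extreme tie probabilities, and the
  exact random-map realisation.
* **Steady states and repair** — brute-force and staged
  (deterministic-modules-first) steady-configuration search with exact
  self-transition probability expressions, and single-edge suggestions
  that make a target configuration absorbing.
* **Simulation** — seeded trajectory sampling with return-time and
  absorption estimators that cross-validate the exact analytics.
* A thin command line (`inst/cli/grnmr.R`) with `analyze`, `atlas`,
  `steady`, `suggest-edges`, `simulate` and `export` subcommands.

## Worked example

The mutual-activation motif (both nodes self-activating and activating each
other) at tie probabilities $p = q = 1/2$:

```r
library(grnmr)

m <- two_node_model("+", "+", "+", "+", p = "1/2", q = "1/2")
tm <- transition_model(m)
as_matrix(tm)
#>      --   -+   +-   ++
#> -- 1.00 0.00 0.00 0.00
#> -+ 0.25 0.25 0.25 0.25
#> +- 0.25 0.25 0.25 0.25
#> ++ 0.00 0.00 0.00 1.00

chain_analysis(tm)
#> <grn_chain> absorbing_extended; 2 ergodic set(s), 2 transient state(s)

fundamental_matrix(tm)[, ]
#>     -+  +-
#> -+ 1.5 0.5
#> +- 0.5 1.5
```

The all-OFF and all-ON states are fixed points; from either tied state the
chain spends on average $3/2$ steps in it and $1/2$ in the other before
absorption (row sums 2 — the expected time to reach a fixed point).

The yeast cell-cycle network with the input Cln3 clamped OFF has exactly one
steady configuration — the biological G1 state, only Cdh1 and Sic1 ON —
which is steady but not absorbing because the MBF and SBF modules tie there:

```r
net <- yeast_network("mr_pruned", clamp_input = "off")
steady_configurations(net)[, c("configuration", "self_prob_expr", "self_prob")]
#>   configuration self_prob_expr        self_prob
#> 1 ----+---+--   (1-p[MBF])*(1-p[SBF])      0.25

dplyr::filter(suggest_stabilizing_edges(net, yeast_g1("spin")),
              sign > 0, source %in% c("Cln1_2", "Clb5_6"))[, 1:3]
#>   fixes source  sign
#> 1 MBF   Clb5_6     1
#> 2 MBF   Cln1_2     1
#> 3 SBF   Clb5_6     1
#> 4 SBF   Cln1_2     1
```

The suggestions include the two biologically documented feedback edges
Cln1/2 → SBF and Clb5/6 → MBF; `yeast_network("revised")` carries them, and
with the input clamped OFF the G1 state becomes the unique attractor of the
1024-state chain.

See `vignettes/majority-rule-networks.Rmd` for the full methods account.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package, the
deterministic-module steady-state census of the yeast network (the number
of core assignments discarded by the staged search) and the support-size
count of an in-phase two-node model at generic tie probabilities, and
writes them as JSON.
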