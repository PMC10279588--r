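---
title: "Critical benefit-to-cost ratios and single-edge graph surgery: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Critical benefit-to-cost ratios and single-edge graph surgery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphsurgery)
```

## The model

The package studies the donation game — a donor pays a cost $c > 0$ so
that the recipient gains a benefit $b > c$ — on a connected, undirected,
weighted network of $N$ individuals, evolving by death–birth updating:
a node $i$ is chosen to die uniformly at random and adopts the type of a
neighbor $j$ selected with probability proportional to
$w_{ij} R_j(\mathbf{x})$, where $R_j = 1 + \eta f_j$ is the reproductive
rate, $f_j = -c\,x_j + b \sum_k p_{jk} x_k$ the neighbor-averaged payoff,
and $\eta \ge 0$ the selection strength.  Under weak selection
($\eta \to 0$) the fixation probability of cooperation from a uniformly
placed single cooperator expands as

$$\rho_C = \frac{1}{N} + \frac{\eta}{2N}\bigl[-c\,\tau_2 + b(\tau_3 - \tau_1)\bigr] + O(\eta^2),$$

so selection favors cooperation ($\rho_C > 1/N$) exactly when
$b/c$ exceeds the **critical benefit-to-cost ratio**

$$(b/c)^* = \frac{\tau_2}{\tau_3 - \tau_1}.$$

The $\tau_k = \pi (P^k \circ T)\mathbf{1}$ are expected coalescence
times between the two ends of a $k$-step stationary random walk;
$P = D^{-1}W$ is the simple random-walk transition matrix,
$\pi_i = s_i / S$ its stationary distribution, and $T$ solves the pair
system $t_{ij} = 1 + \tfrac12\sum_k (p_{ik} t_{jk} + p_{jk} t_{ik})$,
$t_{ii} = 0$, describing two walkers of which one (picked with
probability $1/2$) moves per step.

```{r}
tau_summary(fixture("cycle", 6)) # closed forms: (5, 4, 6), (b/c)* = 4
```

On a $k$-regular graph the summaries have closed forms
($\tau_1 = N-1$, $\tau_2 = N-2$, $\tau_3 = N + N/k - 3$, so
$(b/c)^* \to k$ as $N \to \infty$); `regular_reference()` exposes them
as an independent oracle and the test suite holds the exact solver to
them at $10^{-8}$.

## Exact computation

`coalescence_times()` solves the pair system in its compact
$N(N-1)/2$-unknown symmetric form.  The package also assembles the
redundant $N^2$-dimensional row-major vectorization
$M\,\mathrm{vec}(T) = d$ (`coalescence_system_redundant()`), which is
the form the perturbation theory is phrased in.  One convention had to
be fixed here: for an ordered pair $(i, j)$ with $i > j$ the redundant
row repeats the symmetrized pair equation (all coefficients placed on
upper-triangle positions) with right-hand side 1, rather than pinning
$t_{ij} - t_{ji} = 0$; this matches a right-hand side that is 1 off the
diagonal and 0 on it, and gives the perturbed system matrix exactly
$4N - 6$ structurally nonzero derivative rows.  The two formulations
agree to solver precision and are cross-checked in the tests.

Numerical choices: the compact system is solved by dense LU up to
`dense_limit` pair unknowns (default 15000, about $N = 174$) and by a
sparse LU beyond; the defining equations are re-evaluated at the
solution and a maximum-norm residual above $10^{-6}$ is an error
(observed residuals are below $10^{-10}$).  Degenerate cases are
flagged rather than returned as NaN: when $\tau_3 = \tau_1$ (e.g. the
4-cycle) the ratio is reported as signed infinity with
`degenerate = TRUE`, and a negative $(b/c)^*$ means no benefit-to-cost
ratio favors cooperation.  Bipartite graphs are accepted: the
one-walker-per-step coalescence dynamics is aperiodic even when the
single walk is periodic.

## First-order perturbation theory

For a perturbation of one edge weight $w_{i_0 j_0}$ by $\varepsilon$,
the package computes the exact first-order objects:

* $\Delta\pi_i = (\delta_{i i_0} + \delta_{i j_0})/S - 2\pi_i/S$;
* $\Theta^{(k)}$ with $P^k(\varepsilon) = P^k + \varepsilon\Theta^{(k)} + o(\varepsilon)$,
  both entrywise and through the product rule
  $\Theta^{(2)} = \Theta^{(1)}P + P\Theta^{(1)}$ (the two forms are
  tested equal at $10^{-10}$);
* $\mathrm{vec}(\Delta T) = -M^{-1}\,\Delta M\,\mathrm{vec}(T)$, where
  each row of $M$ is affine in the entries of $P$, so $\Delta M$ is the
  same assembly evaluated on $\Theta^{(1)}$ and its action collapses to
  $v_{ij} = -\tfrac12[(\Theta^{(1)}T)_{ij} + (\Theta^{(1)}T)_{ji}]$,
  touching only the $4N-6$ structurally nonzero rows ($4N-6$ counts the
  pattern: at a degree-one endpoint the transition row is pinned at 1,
  so its derivative rows cancel numerically and fewer rows realize);
* $\Gamma_k = \Delta\pi(P^k \circ T)\mathbf{1} + \pi(\Theta^{(k)} \circ T)\mathbf{1} + \pi(P^k \circ \Delta T)\mathbf{1}$
  and the slope
  $\Delta(b/c)^* = [(\tau_3-\tau_1)\Gamma_2 - \tau_2(\Gamma_3-\Gamma_1)]/(\tau_3-\tau_1)^2$.

Every object is validated against central finite differences of the
fully recomputed quantity, with the residual decaying as $O(h^2)$.

`perturbation_workspace()` performs the one-time precomputation.  Two
solve handles are provided.  The dense handle materializes the inverse
of the compact system once, after which a per-edge slope query costs a
thin column extraction and $O(N^2)$ arithmetic — well inside the
$O(N^3)$ per-edge contract — and is the default up to `dense_limit`.
The sparse handle keeps a sparse LU factorization instead and trades
per-query speed for $O(\mathrm{nnz})$ memory on large networks; it was
measured substantially slower to factor at $N = 100$ (fill-in in the
pair system is heavy), which is why the dense handle is the default at
the scales studied here.  On either handle, no per-edge query triggers
a fresh factorization; the workspace counts factorizations and solves
(`ws$stats`) and the tests assert the count stays at one.

Self-loop perturbation ($i_0 = j_0$) is rejected: the strength
bookkeeping for that case is ambiguous and no generator produces
self-loops.

### Exact finite updates without refactorization

Surgery experiments need the *exact* $(b/c)^*$ after a finite change
(e.g. full removal, $\varepsilon = -1$), not just its linearization.
Because the compact system matrix changes in at most $2N - 3$ rows per
perturbed pair, the perturbed solve is obtained from the base handle by
an exact low-rank (Woodbury) correction (`tau_summary_for()`).  This is
an algebraic identity, not an approximation; the tests hold it equal to
fresh full solves at $10^{-8}$.  The same route accelerates the
sequential-removal baselines, where networks differ from the base by a
handful of edges.

## Synthetic generators as study conditions

The generators reproduce the four synthetic network families at their
standard configurations, which are fixed as the package's study
conditions rather than tuning knobs:

* **ER**: $N = 100$, exactly 300 edges drawn uniformly among the 4950
  pairs; whole graphs rejection-sampled until connected (the retry
  count is recorded in the generator metadata).
* **BA**: growth from the 4-node star, $m = 3$ targets per new node
  drawn sequentially without replacement with degree-proportional
  probabilities (renormalized after each draw, so no multi-edges);
  edge count is deterministic: 291 at $N = 100$, 891 at $N = 300$.
* **Planted 2-partition**: $p_{\mathrm{in}} = 0.11$,
  $p_{\mathrm{out}} = 0.01$, theoretical mean degree 5.89.
* **LFR-style**: degree exponent $\gamma = 3$ (lower cutoff tuned so
  the expected degree is 6, upper cutoff 100), community-size exponent
  $\kappa = 2$ — an unusual value, kept as stated — mixing parameter
  $\bar\mu = 0.1$.  No LFR generator is available in the R stack used
  here, so the package implements its own construction: truncated
  power-law degree and community-size sampling, community assignment
  respecting internal-degree capacity, stub matching with a few
  deficit-repair rounds, rejection until connected.  Realized mean
  degrees land within $\pm 1$ of the target and the inter-community
  edge fraction within $\pm 0.05$ of $\bar\mu$; community membership is
  kept in the generator metadata.

What the generators do *not* emulate: weighted empirical contact
structure, degree–degree correlations beyond what the models induce,
and the specific realizations behind published numbers.  Passing tests
therefore certify the method on these model classes, not on any
particular empirical network; empirical networks enter only through
user-supplied edge lists (`read_edgelist()`).

## Surgery experiments

`correlation_experiment()` compares, over every eligible pair, the
slope $\Delta(b/c)^*$ with the exactly recomputed change under full
removal ($\varepsilon = -w$), unit addition, or enhancement of a unit
edge to weight 2.  Bridges are excluded from removal — the perturbed
ratio is undefined on a disconnected graph — with the exclusion count
reported; the paper-scale instances have at most a few.  Pearson $r$
and its p-value come from `stats::cor.test`.

On regenerated instances at $N = 100$ the removal correlations land
near $-0.8$ to $-0.87$ across ER/BA/RP/LFR and the enhancement
correlations above 0.95, reproducing the pattern that the linear theory
ranks removals and enhancements well while addition (whose response is
strongly nonlinear in $\varepsilon$) is predicted poorly.  The sweep
helper quantifies this: enhancement curves have markedly smaller
chord deviation than removal curves.

`greedy_removal()` removes, five times by default, the non-bridge edge
with the largest slope (ties: lexicographically smallest pair — the
choice is arbitrary and fixed for reproducibility), recomputing all
slopes on the reduced network each step.  The baseline
`degree_heuristic_removal()` removes the edge with the largest degree
sum $k_i + k_j$, enumerating all tie-resolution scenarios up to a cap
(64 by default; beyond it a seeded uniform subsample of branches is
kept).  Each step also records whether scoring by the degree product
$k_i k_j$ would select the same tie set: this holds on the BA class but
can fail on ER instances, where degree pairs such as $(3, 9)$ and
$(6, 6)$ tie on the sum but not on the product — so the product-rule
agreement is asserted only for the scale-free class.  On the tested
classes the slope-guided trajectory decreases $(b/c)^*$ at least as
much as the average degree-sum trajectory, with ratios around
1.0–1.01 at $N = 100$ (the published factors at $N = 300$ are about
1.01–1.05; the $N = 300$ runs are reproducible with this package but
are kept out of the default suite for runtime).

## Dynamics validators

Two independent routes confirm that the coalescence machinery predicts
the actual stochastic dynamics.  `exact_fixation_small()` builds the
full $2^N$-state absorbing Markov chain of the death–birth process and
solves absorption exactly (capped at $N \le 12$); its $\eta$-derivative
at $\eta = 0$ matches $\frac{1}{2N}[-c\tau_2 + b(\tau_3-\tau_1)]$ to
$10^{-3}$ relative error, the sign of $\rho_C - 1/N$ flips at
$(b/c)^*$, and at neutrality the per-start fixation probabilities equal
$\pi_i$ exactly — a sharper statement than the uniform $1/N$ average.
`simulate_fixation()` is the Monte-Carlo counterpart with per-replicate
counter-based seeding; estimates agree with the exact chain within
three standard errors.  One convention is worth noting: the
neighbor-averaged payoff of the update rule absorbs the
donor/recipient role-halving, and any constant factor in $f$ cancels
from $(b/c)^*$, so no separate factor-of-two appears anywhere.

Since payoffs are bounded in $[-c, b]$, reproductive rates stay
positive whenever $\eta < 1/c$; a nonpositive rate raises an error
advising a smaller $\eta$ rather than producing negative selection
probabilities.  Because $\eta \ge 0$ is enforced, $\eta$-derivative
checks use one-sided $O(h^2)$ differences.

## Problem sizes and limitations

The default suite runs the full correlation experiments at the paper
scale $N = 100$ (one seed per class; two extra seeds at $N = 60$),
finite-difference and oracle batteries on 20 random graphs with
$N \le 12$, and the $2^N$ validator at $N \le 8$ — sizes chosen so the
whole suite completes in minutes on one core while still exercising
every claim at its published scale at least once.  Known limitations:
directed or signed graphs, simultaneous multi-edge perturbation slopes
(finite multi-edge *updates* are exact via `tau_summary_for()`),
second-order corrections in $\varepsilon$, update rules other than
death–birth, and non-donation payoff matrices are all out of scope.
The dense workspace needs $O(N^4)$ memory ($\approx$ 200 MB at
$N = 100$) and is the right tool up to a few hundred nodes; beyond
that the sparse handle trades speed for memory.
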