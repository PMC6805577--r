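---
title: "Multi-state logical network models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-state logical network models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvnet)
```

## The modeling framework

`mvnet` implements time-discrete, state-discrete dynamical systems over a
regulatory wiring diagram — generalized Boolean networks in which each node
$x_i$ takes one of $n_i$ ordinal states $\{0, 1, \dots, n_i-1\}$ (by default
$2 \le n_i \le 5$) rather than just ON/OFF. This class of qualitative model
is widely used for gene regulatory networks when kinetic parameters are
unavailable: the states stand for coarse expression levels
(OFF/ON, LOW/MEDIUM/HIGH), and the dynamics are driven entirely by logical
rules, so the reachable phenotypes depend on the network architecture rather
than on rate constants.

Every node carries a total transition table — its *big state transition
table* (BSTT) — mapping each combination of its regulators' states plus its
own current state to its next state. Unless a row is overridden, the table
is auto-generated by the **additive rule**:

$$
x_i(t+1) \;=\; \operatorname{clamp}\!\Big( x_i(t)
  \;+\; \sum_{j \in A_i} x_j(t) \;-\; \sum_{j \in I_i} x_j(t) \Big),
\qquad
\operatorname{clamp}(v) = \min(\max(v, 0),\, n_i - 1),
$$

where $A_i$ and $I_i$ are the activators and inhibitors of node $i$, and a
`custom` edge replaces $\pm x_j(t)$ with an arbitrary per-state signed
contribution. Each BSTT row reads as a biological statement — "if A is high
and B is low and C is low now, C becomes medium next" — which is why the
table, not a formula language, is the primary modeling surface. Any row can
be overridden, so arbitrary update functions (synergy, thresholds, logic
gates) are expressible; the additive default is only the starting point.

### Numerical choices in the update rule

Several details of the additive rule are genuinely open design choices; the
ones made here, and why:

* **One clamp, applied to the total.** Per-edge effects are accumulated as
  unclamped signed integers and clamped once against the target's range.
  Clamping each edge separately before summing is a different (and less
  expressive) operator: with a 3-state target, an activator at 2 and an
  inhibitor at 2 cancel exactly under total-clamping, whereas per-edge
  clamping could not represent the intermediate overshoot. Single "edge
  tables" presented to a user are derived views `clamp(self + delta)`,
  never the stored representation.
* **The self input is always present**, as the last BSTT column, even when
  an override ignores it. This keeps every table's input order predictable
  (edge sources in declaration order, then self) and makes the no-input
  case consistent: with an empty sum the rule degenerates to
  `clamp(self) = self`, so **nodes with no incoming edges hold their
  state** — they behave as boundary conditions, not as decaying species.
* **No rescaling across unequal state counts.** A 2-state regulator feeding
  a 4-state target contributes its raw state (0 or 1); the target-side
  clamp is the only range adjustment. Automatic rescaling would silently
  change the arithmetic of every mixed-radix model; users who want a
  stronger or weaker coupling write a `custom` contribution table, which
  makes the rescaling explicit and auditable.
* **A self-edge duplicates the self column.** Declaring an edge from a node
  to itself adds a second, signed copy of its state to the sum (so a
  self-inhibiting 3-state node computes `clamp(c - c) = 0` for every `c`).
  The trailing self column remains; both columns read the same state.
* **The 5-state cap is policy, not mathematics.** `max_states` is a
  validation parameter (default 5, the conventional ceiling for ordinal
  expression levels) and can be raised everywhere it appears, including as
  `--max-states` on the command line.

## Synchronous dynamics and state indexing

All nodes update simultaneously: the global successor map
$F(x) = (f_1(x), \dots, f_n(x))$ is total and deterministic, so the state
space is a *functional graph* — every one of $N = \prod_i n_i$ states has
exactly one out-edge, and the attractors (steady states and limit cycles)
are precisely the graph's cycles. Asynchronous and stochastic update
schemes are deliberately out of scope; they answer different questions and
are served by other tools.

States are identified with mixed-radix integers: in canonical node order
(declaration order, which also fixes tuple order everywhere),
$\text{index}(x) = \sum_i x_i \prod_{j>i} n_j$. The first node is the most
significant digit, so lexicographic order of tuples equals numeric order of
indices. Enumeration order has no effect on the attractor decomposition; it
only fixes reporting and tie-breaking, and is documented so results are
bit-reproducible.

### Attractor search

`find_attractors()` enumerates exhaustively. The successor of every state
is computed once into a memoized array (in chunks of $10^6$ states, so
memory stays proportional to the chunk, not to $N \times n$); then each
not-yet-classified state starts a walk along stored successors until it
meets either a state on the current walk (a new cycle: the walked suffix)
or an already-classified state (an existing basin). The whole walked path
is assigned to that attractor. Every state is visited a bounded number of
times, so the decomposition is linear in $N$ — the 559,872-state floral
scaffold, and perturbations of it, are comfortably inside interactive use.

Guard rails, both overridable: analysis refuses state spaces above
`analysis_cap` ($10^7$ by default, the point where the successor array and
assignment vectors start to dominate desktop memory), and
`state_space_graph()` refuses drawings above `graph_cap` (2600 states by
default — beyond that a node-link diagram stops being readable; raise it if
you only want the edge list).

Reporting conventions: attractors are numbered by descending basin size,
ties broken by the smallest state index on the cycle; cycles are rotated to
start at their smallest state index; basin percentages are kept at full
precision internally and rounded to one decimal in printed and exported
output. `sum(basin_size)` always equals $N$ — the basins partition the
state space.

## Experiments: knockouts, knockdowns, overexpression

An `experiment()` pins nodes to constant states. `apply_experiment()`
replaces each pinned node's update function with the constant — the pin
semantics, not a display filter: the perturbed system is a first-class
dynamical system and its attractor enumeration is complete, including any
limit cycles, with basins that still partition the full state space
(states that start with the "wrong" pinned value satisfy the pin from the
first update on). Analyses of pinned models say so in their printed report.

Two consequences of pinning by constant update, rather than deleting the
node's edges:

* **Overexpression works.** A node pinned above 0 keeps feeding its pinned
  value to its targets, so `experiment(AG = 2)` models constitutive high
  expression, not just absence. Pinning to 0 reproduces the classical
  knockout, where incoming and outgoing influences are inert.
* **Releasing a pin is exact.** `release_node()` removes the constant; with
  no pins left, the compiled system is identical to the wild type.

## File formats

* **Model JSON** (`schema_version` "1.0"): nodes with ordered state-label
  lists, edges with sign and optional contribution tables, row overrides,
  and optional experiments. States are written as labels, with the integer
  mapping fixed by label order, so files are human-editable and robust to
  relabeling. Serialization is canonical — the same model always produces
  the same bytes — and unknown fields survive a round trip. Validation runs
  on load and names the offending element.
* **Attractor CSV** (RFC 4180, UTF-8): one row per attractor state, grouped
  by attractor, each node as both label and integer, basin size and
  percentage; sorted like the analysis summary.
* **DOT / GraphML** state graphs via `write_state_graph()`, with state
  labels and an `on_cycle` attribute for styling; GraphML output re-parses
  with igraph.

Published logical-rule tables load through `read_rules()`: one JSON entry
per node with its regulator list and full truth table. The loader installs
zero-contribution custom edges plus a complete set of overrides, i.e. it
interprets a published table as the node's entire rule (the output is
repeated across the self column unless the node lists itself as an input).
That "full override" interpretation is one of two defensible readings of
table-based model descriptions — the alternative, fitting published tables
as deviations from the additive default, cannot represent tables whose
support differs from the wiring — and is the one used here.

## The floral case study

`floral_scaffold()` reproduces the node-and-state structure of the
15-gene *Arabidopsis thaliana* floral organ-fate network of Espinosa-Soto,
Padilla-Longoria & Alvarez-Buylla (2004): eight binary and seven ternary
nodes, hence $2^8 \cdot 3^7 = 559{,}872$ global states. The published
logical rules belong to that paper and are **not redistributed** here;
`inst/extdata/floral-rules-template.json` is a transcription skeleton with
the fifteen node entries ready to fill. With a completed transcription,

```r
model <- floral_scaffold("floral-rules.json")
wt  <- find_attractors(compile_model(model))
ap2 <- find_attractors(apply_experiment(model, experiment("AP2", name = "ap2")))
```

runs the wild-type and *ap2* loss-of-function analyses over all 559,872
initial conditions. The corresponding checks in `test-acceptance.R` assert
the published attractor counts for this model (40 wild-type and 28 *ap2*
steady states, no limit cycles) and therefore require a local
transcription; without one they fail with a message saying exactly that.

## The random-model generator

`random_model()` draws wiring diagrams for property-based testing:
Erdős–Rényi-style edges over ordered node pairs (self-edges included) with
probability `edge_probability`, each edge inhibiting with probability
`inhibitor_fraction`, state counts sampled from `state_count_choices`, and
optionally a fraction of BSTT rows replaced by uniform random outputs. The
defaults (`edge_probability = 0.25`, `inhibitor_fraction = 0.3`,
states 2–3) give the sparse, mixed-sign, mostly-additive networks typical
of hand-built qualitative models. Randomness comes from R's Mersenne-
Twister stream with fixed `normal.kind` and `sample.kind`, seeded
explicitly, so a seed identifies a model across platforms and R versions;
the caller's RNG state is saved and restored.

What the generator does **not** emulate: realistic degree distributions
(hubs), enriched feedback or feed-forward motifs, correlated rule
structure, or the biological bias toward canalizing rules. Passing the
property suites therefore demonstrates algorithmic correctness — exact
agreement with an independent brute-force decomposition, conservation of
basin sizes, additive-rule conformance, pin invariance — on a broad sample
of small models, not biological validity of any particular network.

## Validation strategy and problem sizes

The test suite checks every hand-derivable quantity of the bundled
three-node example (all 12 BSTT rows; 8 steady states with basins
3,3,1,1,1,1,1,1; the knockout's 4 steady states; trajectories), and then
property-checks random models against an *independent* oracle that shares
no code with the implementation: successors re-derived directly from the
model definition and the functional graph decomposed by composition
squaring ($F^{2^k}$ with $2^k \ge N$ maps every state onto its cycle; the
cycle states are exactly the image). The acceptance suite runs 200 seeded
models of 3–5 nodes with 2–3 states each (at most $3^5 = 243$ states, a
size chosen so the quadratic-ish oracle stays instant while still
exercising mixed radices, self-edges, overrides, and limit cycles); the
whole suite completes in well under a minute.

## Known limitations

* Synchronous, deterministic semantics only.
* Exhaustive enumeration only: no sampling-based attractor estimation and
  no symbolic (SAT/BDD) methods, so state spaces beyond ~$10^7$ states are
  out of reach by design.
* No SBML-qual / BoolNet / GINsim import or export yet; the JSON schema is
  this package's own.
* Perturbations are constant pins; time-varying perturbations and
  edge-specific (rather than node-specific) knockouts are not modeled.
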