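# mvnet

Multi-state logical network models with exhaustive attractor analysis.

`mvnet` is for biologists and modelers who want to ask what phenotypes a
regulatory network can sustain — without rate constants. A model is a wiring
diagram: nodes with a small number of ordinal states (2–5; e.g. OFF/ON or
LOW/MEDIUM/HIGH) and signed edges. Each node updates by a total transition
table that is auto-generated from the wiring by the additive rule

```
x_i(t+1) = clamp( x_i(t) + Σ_{j activates i} x_j(t) − Σ_{j inhibits i} x_j(t) ),
clamp(v) = min(max(v, 0), n_i − 1)
```

and any table row can be overridden, so arbitrary logical rules (published
truth tables included) are expressible. All nodes update synchronously, so
the state space of `N = Π n_i` global states is a functional graph whose
cycles are exactly the model's **attractors**: steady states (candidate
phenotypes) and limit cycles (oscillations). `mvnet` enumerates the whole
space, reports every attractor with its **basin of attraction** (the share
of initial conditions that reach it — a proxy for how likely that phenotype
is), and runs in-silico experiments by pinning nodes to constant states
(knockout at 0, knockdown/overexpression at higher states), which yields
the complete and correct perturbed attractor set.

Results come back as tibbles (`tidy()`, `glance()`), plots (`autoplot()`,
`plot_state_space()`), and files (JSON models, CSV summaries, DOT/GraphML
state graphs). A command-line front door covers the
validate → experiment → analyze → export workflow.

## A worked example

A three-node network: A (2 states) activates C (3 states), B (2 states)
inhibits it, so C follows `C' = clamp(A − B + C)` while the input-free
nodes A and B hold their states.

```r
library(mvnet)

m <- logic_model("toy") |>
  add_node("A", states = 2) |>
  add_node("B", states = 2) |>
  add_node("C", states = 3) |>
  add_edge("A", "C", "activate") |>
  add_edge("B", "C", "inhibit")

m |> compile_model() |> find_attractors()
#> <logic_analysis> of 'toy': 12 states, 8 attractor(s) (8 steady, 0 cyclic)
#> # A tibble: 8 × 4
#>   attractor cycle_length basin_size basin_pct
#>       <int>        <int>      <int>     <dbl>
#> 1         1            1          3      25
#> 2         2            1          3      25
#> 3         3            1          1       8.3
#> 4         4            1          1       8.3
#> 5         5            1          1       8.3
#> 6         6            1          1       8.3
#> 7         7            1          1       8.3
#> 8         8            1          1       8.3
```

Eight steady states, no oscillations. The two basin-3 attractors are the
states the inputs force: with A on and B off, C is driven to its maximum
(1,0,2); with B on and A off, to its minimum (0,1,0); each collects the
three initial C levels. In the six states with A = B the inputs cancel and
C freezes where it started — basins of size 1. Basins always sum to the 12
states of the space.

Knocking out B (pinned to 0) removes the inhibition:

```r
m |> apply_experiment(experiment("B", name = "ko_B")) |> find_attractors() |> glance()
#> # A tibble: 1 × 6
#>   model total_states n_attractors n_steady_states n_limit_cycles largest_basin_pct
#>   <chr>        <dbl>        <int>           <int>          <int>             <dbl>
#> 1 toy             12            4               4              0                50
```

and a time course from A on, B off, C off climbs to the (1,0,2) steady
state in two steps:

```r
simulate_model(compile_model(m), c(1, 0, 0))
#> # A tibble: 3 × 5
#>    step index     A     B     C
#> * <int> <dbl> <int> <int> <int>
#> 1     0     6     1     0     0
#> 2     1     7     1     0     1
#> 3     2     8     1     0     2
```

The same analysis from a shell:

```sh
Rscript inst/scripts/mvnet analyze inst/extdata/toy-network.json --knockout B --summary out.csv
```

## The floral case study

`floral_scaffold()` builds the node/state structure of the 15-gene
*Arabidopsis* floral organ-fate network of Espinosa-Soto, Padilla-Longoria
& Alvarez-Buylla (2004, Plant Cell 16:2923) — eight binary and seven
ternary nodes, a state space of 2^8 · 3^7 = 559,872. The published logical
rules are not redistributed here; transcribe them into the template at
`inst/extdata/floral-rules-template.json` and pass the file's path to
`floral_scaffold()` to analyze the full model and its mutants exhaustively
over all 559,872 initial conditions.

## Documentation

The methods vignette (`vignettes/multistate-logical-networks.Rmd`) explains
the update rule and its design choices, the attractor algorithm, the pin
semantics for experiments, the file formats, and what the random-model
generator does and does not emulate.
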