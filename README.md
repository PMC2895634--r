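# plumotif

Joint sequence + secondary-structure motif discovery for RNA-binding
proteins (RBPs) from quantitative binding-affinity data.

Many RBPs bind a short sequence element only in a preferred structural
context — a hairpin loop, an unpaired stretch, a helix, or a
bulge/internal-loop region. `plumotif` learns both preferences at once
from RNAcompete-style data: per-sequence binding-affinity estimates over a
designed pool of short RNAs.

## The model

Each base of every RNA is annotated with a probability distribution over
structural-context letters — the PLUM alphabet: **P**aired, hairpin
**L**oop, **U**nstructured/external, **M**iscellaneous (bulge, internal
loop, multiloop) — estimated by stochastic sampling from the Boltzmann
ensemble of secondary structures (1,000 samples per sequence by default).
A binding site of width *w* is scored as

> p(site) = σ(b₁ + Σⱼ Θ[xⱼ, j]) · σ(b₂ + Σⱼ Σₐ Γₐ πₐ(j))

a position weight matrix Θ for the sequence and a per-context preference
vector Γ weighted by the site's annotation profile π; a whole sequence's
score is the noisy-OR over all windows, N = 1 − Π(1 − pᵢ). Parameters are
fitted by regularized least squares against measured affinities
(L-BFGS-B, slope constrained positive, multi-restart width scan 4–12,
selection by training AUC-PR) and evaluated by two-fold Set A / Set B
cross-validation with bootstrap significance.

A built-in generator produces synthetic RNAcompete-style pools (stem-loop
plus weakly structured groups, 29–38 nt, ≤12-nt shared substrings) with
ground-truth affinities from a known planted model, so the entire method
is testable end to end without downloads.

## Worked example

```r
library(plumotif)

pool  <- simulate_pool(seed = 1)              # 2,000 stem-loop + 2,000 weak
train <- dplyr::filter(pool$records, set == "A")
test  <- dplyr::filter(pool$records, set == "B")

fit <- fit_motif(train, training_config(widths = 4:8, base_seed = 1))
glance(fit)
#> # A tibble: 1 × 7
#>   width subset objective train_aucpr converged lambda_reg best_context
#>   <int> <chr>      <dbl>       <dbl> <lgl>          <dbl> <chr>
#> 1     5 full        16.2           1 TRUE            0.01 L

context_preference_ratios(fit$model)
#> <context_preference> best letter: L ( convention: sum )
#> # A tibble: 4 × 4
#>   letter   gamma     pure_term         ratio
#>   <chr>    <dbl>         <dbl>         <dbl>
#> 1 P      -3.78   0.00000000260 0.00000000271
#> 2 L       0.795  0.958         1
#> 3 U      -1.50   0.000235      0.000245
#> 4 M       0.0915 0.404         0.422

evaluate_fit(fit, test)
#> [1] 1
```

The generator planted a width-6 consensus at the 5′ end of hairpin loops;
the fit recovers the hairpin loop (L) as the preferred context — the
paired and unstructured contexts score 10⁻⁴ to 10⁻⁹ of its scale
factor — and separates
held-out positives from negatives with AUC-PR 1.0, while the
structure-naive single-letter ablation (`ablation_single_letter()`)
reaches about 0.72 on the same data.

Each fitted model exports a PFM for logo rendering (`pfm_for_logo()`,
`write_meme_pfm()`), relative context-preference ratios
(`context_preference_ratios()`), and a per-position preferred-context
track averaged over the top-scoring windows
(`preferred_context_track()`). `tidy()`, `glance()` and `autoplot()`
methods cover the fit, the model and PR curves.

A thin command-line interface wraps the same functions
(`inst/cli/plumotif`): `simulate`, `annotate`, `train`, `score`,
`evaluate`, `report`, each writing a provenance record beside its
outputs.

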