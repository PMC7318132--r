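# nacprofiler

Near-attack-conformation (NAC) accessibility profiling for cytochrome P450
site-of-metabolism (SOM) selectivity.

## The problem

Cytochrome P450s hydroxylate C−H bonds via hydrogen atom transfer (HAT) to
the iron(IV)-oxo species Compound I. Which site of a substrate is actually
hydroxylated depends on two competing factors:

* **accessibility** — how often the enzyme's binding dynamics place a given
  abstractable hydrogen next to the oxo moiety, and
* **intrinsic reactivity** — the activation barrier for abstracting that
  hydrogen.

Steroids such as testosterone and dihydrotestosterone are the classic hard
case: CYP3A4 hydroxylates testosterone at 6β, 2β, 15β and 1β, while the
aromatase CYP19A1 attacks the chemically *less* reactive angular methyl
site 19 — the enzyme environment overrides intrinsic chemistry.

`nacprofiler` is for structural bioinformaticians and modellers who have a
conformational ensemble of a P450–substrate complex (e.g. MD snapshots as a
multi-model PDB) and want a quantitative, reproducible accessibility and
selectivity analysis.

## The method

A frame places a hydrogen in a **near-attack conformation** when

```
2.0 Å ≤ d(H, oxo) ≤ 3.5 Å   and   θ(H–oxo–Fe) > 120°
```

(distance bounds inclusive, angle strict; both configurable). A site is
*accessed* in a frame when at least one of its candidate hydrogens (a
methyl site owns all three) is in a NAC. The **accessibility profile**
reports per site

```
percentage(s) = 100 · n_events(s) / Σ_t n_events(t)
```

where an event is an accessed (frame, site) pair. Intrinsic reactivity
enters as Boltzmann weights of the per-site activation barriers ΔE‡
(kcal/mol),

```
w_s = exp(−ΔE‡_s / RT) / Σ_t exp(−ΔE‡_t / RT),   R = 1.987204×10⁻³ kcal mol⁻¹ K⁻¹
```

and the **selectivity score** is the normalized product
`score_s ∝ percentage_s · w_s` — accessibility gates reactivity, so a
reactive but buried site scores zero. The package ships the transcribed
testosterone HAT barrier table (plain and dispersion-corrected) and the
published CYP3A4 turnover rates as data fixtures, plus per-residue ensemble
RMSF for receptor-flexibility analysis and a seeded synthetic trajectory
generator with closed-form ground truth.

## Worked example

```r
library(nacprofiler)

## a synthetic 2000-frame ensemble in which site 19 is exposed in 45 % of
## frames and 6β in 5 % (ground truth 90 % / 10 % of access events)
spec <- syntheticSpec(c("19" = 0.45, "6β" = 0.05), nFrames = 2000, seed = 42)
traj <- simulateTrajectory(spec)
toy  <- buildToyTopology(spec)

prof <- accessibilityProfile(traj, toy$map, toy$center)
prof
#> AccessibilityProfile: 2000 frames, 977 with access, 977 events (denominator: events)
#>  site events percentage stereoClass
#>    19    882  90.276356      methyl
#>    6β     95   9.723644        beta
```

The profile recovers the ground truth to binomial error: 90.3 % vs 90 %,
9.7 % vs 10 %, and 977/2000 ≈ 0.49 frames with access vs the expected 0.5.
Combining it with dispersion-corrected barriers (6β is by far the most
reactive site, Boltzmann weight 0.9989 at 298.15 K):

```r
w <- boltzmannWeights(loadBarrierTable(), "d3")
combineSelectivity(prof, w[siteLabels(toy$map)])
#>   site accessibility       weight        score rank
#> 1   6β      9.723644 9.989480e-01 1.000000e+00    1
#> 2   19     90.276356 2.954442e-10 2.745855e-09    2
```

Although site 19 is accessed nine times more often, its HAT barrier is
13 kcal/mol higher, so 6β dominates the combined ranking — the same
competition logic that decides steroid hydroxylation selectivity. The
barriers also rank exactly inversely to the published CYP3A4 turnover
rates:

```r
tb <- loadBarrierTable()
spearmanRank(loadExperimentalRates(), setNames(tb$d3, tb$site))
#> [1] -1
```

A command-line wrapper covering `simulate`, `profile`, `rmsf` and
`selectivity` is installed at `inst/cli/nacprofiler.R`:

```sh
Rscript inst/cli/nacprofiler.R profile --trajectory traj.pdb \
    --sitemap sites.yaml --out results/
```

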