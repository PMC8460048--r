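# sacchsim

Stochastic, monomer-resolved simulation of lignocellulose saccharification.

Breaking plant cell wall material down into fermentable sugars is the core
step of second-generation biofuel production, and it is slow and expensive
because the substrate fights back: cellulose microfibrils are wrapped in
hemicellulose and lignin, parts of the polymers are crystalline and hard to
digest, and lignin both walls off bonds and adsorbs the enzymes themselves.
`sacchsim` is an R package for researchers who want to dissect these effects
*in silico*: it simulates the digestion of a single microfibril — a
quasi-hexagonal bundle of 36 cellulose chains (DP 200) surrounded by
gap-ridden hemicellulose/lignin shells — at the resolution of individual
monomers and glycosidic bonds.

## The model in brief

Four enzyme classes act on the substrate, each with its own mechanism:
endoglucanase (EG) cuts internal cellulose bonds (never the two outermost at
each fragment end), cellobiohydrolase (CBH) attaches to exposed chain ends
and processively releases cellobiose at

```
k_CBH = N_steps / t_CBH ≈ 50 / 90 s ≈ 0.56 s⁻¹ ≈ 2000 h⁻¹,
```

β-glucosidase (BGL) cleaves cellobiose into two glucose, and xylanase (XYL)
cuts xylan anywhere.  A bond reacts only when it is *accessible* — exposed to
the medium laterally or flanked by an already digested bond.  Crystalline
regions (the central `round(frac · N_bonds)` bonds of each chain) digest at a
reduced rate `r_c,a = d_crystalline / d_amorphous ∈ [0, 1]`, lignin blocks
the bonds beneath its covering monolignols, and a finite monolignol pool
irreversibly adsorbs free enzymes.  The whole system evolves by a
Gillespie-type kinetic Monte Carlo algorithm (direct method, with scheduled
CBH detachments layered in next-reaction style), implemented in C++ for
speed; a full default run takes well under a second.

The package also provides the batch-to-simulation dosage arithmetic
(sub-unit mass/volume bookkeeping and cocktail ratio splits, e.g. 148
enzymes → EG 20, CBH 52, BGL 15, XYL 61), conversion and DP-distribution
observables, low/medium/high pre-treatment severity presets, a hybrid
random/gradient generational fitting procedure for saccharification time
courses, and a seeded synthetic pseudo-experiment generator for recovery
studies.

## A worked example

```r
library(sacchsim)

fib <- microfibril(seed = 1)      # default medium-severity substrate
fib
#> <microfibril> 36 cellulose chains, 200 bonds each; 93 chains total
#>   monomers: 7236 glucose, 1111 xylose, 3343 monolignol (61.9/9.5/28.6%)
#>   crystallinity r_ca: cellulose 0.03, hemicellulose 0.043; structured

run <- simulate_run(fib, cocktail(), run_config(seed = 1))
run
#> <sacch_run> 9281 events, stop: t_end at t=72 h
#>   final conversion: glucan->glucose 93.4%, xylan->xylose 83.7%

subset(run$timecourse, time %in% c(8, 24, 48, 72))
#>    time glucan_pct xylan_pct glucose cellobiose xylose
#> 5     8   41.76341  53.28533    3022        229    592
#> 13   24   77.45992  76.05761    5605         47    845
#> 25   48   88.52957  80.10801    6406         16    890
#> 37   72   93.42178  83.70837    6760        5    930

run$bound_counts
#>  EG CBH BGL XYL
#>  10  23   8  26
```

The substrate realizes the medium-severity composition exactly (7236 glucose
fixes 1111 xylose and 3343 monolignols at 61.9/9.5/28.6%).  Over 72 hours the
glucan→glucose conversion climbs to 93%: the amorphous cellulose goes
quickly, the 19% crystalline core (38 central bonds per chain, digested 33×
slower at `r_c,a = 0.03`) supplies the slow tail, and 67 of the 148 enzymes
end up irreversibly bound to lignin — the monolignol pool (3343/50 ≈ 67
bindings) is exhausted, which is why digestion continues at all.  Cellobiose
stays low because BGL clears it as CBH produces it.

Replicates, sweeps and fitting follow the same pattern:

```r
reps <- simulate_replicates(10, list(), cocktail(), run_config(), master_seed = 1)
sw   <- sweep_lignin(seq(0, 0.5, 0.1), n = 10, cfg = run_config(t_end = 30))
ds   <- generate_pseudo_experiment(c(), "medium", noise_sd = 2, seed = 1)
fit  <- run_fit(ds, param_set(c(frac_cellulose = 0.45), upper = 1),
                fit_config(seed = 1))
```

A thin command-line front end covering `build`, `dose`, `simulate`, `sweep`,
`fixtures` and `fit` ships in `inst/cli/sacchsim.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/sacchsim.R", package = "sacchsim"))')" \
    simulate --severity medium --replicates 10 --seed 1 --out out/
```

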