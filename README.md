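# stripesignal

Tools for studying **honest visual signals** in fish — built around the
facial color mask of territorial cichlids, where a black horizontal stripe
can darken or pale within seconds as a fish's aggressive intent changes.
The package is aimed at sensory/behavioral ecologists who want to run the
full chain from reflectance spectra to social-cost statistics in one place:

1. **Signal design (Stage 1).** A receptor-noise-limited (RNL) visual model
   computes chromatic and achromatic contrasts between color patches as the
   fish's own visual system sees them under depth-attenuated underwater
   light, and tests whether adjacent pattern elements out-contrast
   nonadjacent ones (the signature of a design selected for
   conspicuousness).
2. **Signal message (Stage 2).** Dyadic-contest analysis: dyad matching
   checks, ethogram scoring, a fighting-ability index, winner/loser mixed
   models, and a binomial mixed model linking end-of-contest stripe state to
   dominance.
3. **Signal reliability (Stage 3).** Out-of-equilibrium manipulation
   analysis: mixed models of the aggression received by fish whose stripe
   was artificially darkened or paled (mirror-image stimulation), Tukey HSD
   treatment contrasts, and fold-effect sizes — quantifying the social
   punishment of unreliable signalers.

A seeded synthetic-data generator emulates every input (patch spectra, a
trichromatic-plus-luminance visual system, underwater light, contests,
mirror trials), so the entire pipeline is testable and demonstrable without
access to original measurements.

## The model at the core

A receptor with sensitivity $S_i(\lambda)$ viewing a patch $R(\lambda)$
under illuminant $I(\lambda)$ catches
$Q_i = \int R\, I\, S_i\, d\lambda$, von Kries-adapted to
$q_i = Q_i/Q_i^{\text{white}}$. With log signals $f_i = \ln q_i$ and Weber
fractions $\omega_i = \nu/\sqrt{\eta_i}$, the chromatic distance between
two patches is the receptor-noise-limited contrast (for a trichromat)

$$\Delta S = \sqrt{\frac{\omega_1^2(\Delta f_2-\Delta f_3)^2 +
\omega_2^2(\Delta f_1-\Delta f_3)^2 + \omega_3^2(\Delta f_1-\Delta f_2)^2}
{(\omega_1\omega_2)^2 + (\omega_1\omega_3)^2 + (\omega_2\omega_3)^2}}$$

in just-noticeable differences (JND), and the achromatic contrast is
$\Delta L = |\Delta f_L|/\omega_L$ on a double-cone luminance channel.
Ambient light at depth follows Beer–Lambert attenuation
$I_d(\lambda) = I_0(\lambda)e^{-K(\lambda)d}$, and receptor sensitivities
can be synthesized from $\lambda_{max}$ with the standard A1 visual-pigment
nomogram. See the vignette
(`vignettes/visual-signal-pipeline.Rmd`) for the statistical machinery of
Stages 2–3 and every design decision.

## Worked example

```r
library(stripesignal)

cfg    <- synthetic_config(seed = 1)
system <- gen_visual_system(cfg)
env    <- gen_light_environment(cfg)
system
#> <visual_system> 3 chromatic channels (cone455, cone530, cone565) + luminance
#>   Weber fractions: cone455=0.0707, cone530=0.05, cone565=0.05; luminance 0.05

# Stage 1: are adjacent patches more contrasting than nonadjacent ones?
patches <- gen_conspicuousness_dataset(cfg, n_fish = 20)
records <- pairwise_contrasts(patches, default_adjacency(), system, env)
fit <- adjacency_lmm(aggregate_per_fish(records),
                     response = "chromatic", design = "dominant_only")
fit
#> Linear mixed model: chromatic contrast (identity response), REML
#>       term     F ndf ddf        p
#>  adjacency 69.26   1   9 1.61e-05
```

Adjacency explains chromatic contrast overwhelmingly (F with the classical
containment denominator df of 9 for 10 dominant fish): the mask is built so
that neighboring patches collide chromatically.

```r
# Stage 2: does the stripe state at the end of a contest track dominance?
dyads <- gen_contests(cfg, seed = 2)
stripe_outcome_glmm(dyads, "end")
#> Stripe-state vs contest outcome (binomial GLMM LRT)
#>   chi-squared(1) = 30.202, p = 3.893e-08
#>   odds ratio (win | dark vs pale stripe): 108
```

Losers pale; a dark stripe at the end of the contest is associated with
winning (odds ratio far above 1), while the same test at the start of the
contest is null — the stripe reports current intent, not future outcome.

```r
# Stage 3: is unreliable signaling punished?
trials <- gen_mis_trials(cfg, seed = 3)
fold_effects(trials, seed = 4)
#>                        effect    ratio    ci_lo    ci_hi
#> 1     bouts_darkened_vs_paled 1.580823 1.354447 1.835660
#> 2   bouts_darkened_vs_control 1.977564 1.668865 2.346357
#> 3      bouts_paled_vs_control 1.250971 1.061874 1.477634
#> 4 latency_control_vs_darkened 2.014645 1.628212 2.517176
#> 5    latency_control_vs_paled 1.295646 1.099512 1.525890
```

Fish with manipulated stripes — darkened *or* paled — receive more bouts of
aggression, and faster, than sham-manipulated controls (all ratios above 1
with bootstrap CIs excluding 1): receivers detect and punish signals that
do not match the signaler's state.

`run_all(run_config(out_dir, seed))` executes all three stages and writes
every table as CSV plus a run manifest; a thin command-line wrapper with
`simulate`/`stage1`/`stage2`/`stage3`/`all` subcommands lives at
`inst/cli/stripesignal.R`.

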