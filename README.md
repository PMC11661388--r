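# dotconf

Decision and confidence modelling for multi-alternative dot-numerosity
tasks.

## The problem

In a dot-numerosity task an observer briefly sees a cloud of red, green and
blue dots, reports which colour has the most dots (a 3-alternative choice),
and rates their confidence on a 4-point scale. The paradigm's appeal is
that the stimulus-to-evidence mapping can be written with a *single* free
parameter, which makes it a clean testbed for theories of how confidence is
computed in multi-alternative decisions. `dotconf` is for researchers in
perceptual decision making and metacognition who want to fit, compare, and
simulate these models.

## The models

**Decision model (scalar variability).** The internal activation produced
by *n* dots of one colour is

&nbsp;&nbsp;&nbsp;&nbsp;X<sub>n</sub> ~ N(µ<sub>n</sub>, σ<sub>n</sub>²),&nbsp;&nbsp;µ<sub>n</sub> = n,&nbsp;&nbsp;σ<sub>n</sub> = αn,

with noise coefficient α. The observer samples one activation per colour
and picks the maximum. A 4-parameter extension adds colour-bias multipliers
m<sub>g</sub>, m<sub>b</sub> (red fixed at 1) and a lapse rate λ:
p<sub>i</sub> = (1 − λ)·P(X<sub>i</sub> = max) + λ/3.

**Confidence models.** All three place three fitted criteria on a
continuous confidence variable:

| model | confidence variable |
|---|---|
| `top2diff` | max(x) − max2(x), the top-two evidence gap |
| `bch` | posterior probability the chosen colour truly dominates (dot counts marginalised over an integer grid, 1–200) |
| `pe` | max(x), the chosen option's evidence alone |

They dissociate sharply: `top2diff` is scale-covariant (more dots at fixed
ratios → higher confidence, the *numerosity effect*), `bch` is nearly scale
invariant (no numerosity effect), and `pe` predicts higher confidence when
a *non-dominant* option has more dots.

**Fitting.** Decision parameters are estimated by maximum likelihood from
the choice marginal (exact quadrature probabilities); the three confidence
models are then fitted to the joint (choice, rating) table with the
decision parameters frozen, so all share the same distributional
assumptions and exactly three free parameters. Models are compared by
AIC = −2 log L + 2k, with subject-resampling bootstrap CIs on summed AIC
differences.

## Worked example

Simulate one synthetic subject of the 12-condition experiment (1,440
trials, true α = 0.27, λ = 0.06, confidence generated by `top2diff`), then
run the full pipeline:

```r
library(dotconf)

design <- build_design("expt2")
spec   <- subject_spec("s01", design, decision_params(0.27, lapse = 0.06),
                       model = "top2diff", seed = 42)
trials <- simulate_subject(spec)
tab    <- response_table(trials, design)

fit_decision_1p(choice_table(tab), design)
#> model: decision_1p
#> params: alpha = 0.3006
#> logL = -1140.938, AIC = 2283.876 (k = 1, restarts = 2, converged = TRUE)

fit4 <- fit_decision_4p(choice_table(tab), design, seed = 1)
fit4
#> model: decision_4p
#> params: alpha = 0.2598, m_green = 1.013, m_blue = 0.9943, lapse = 0.0595
#> logL = -1137.617, AIC = 2283.234 (k = 4, restarts = 2, converged = TRUE)
```

The 1-parameter fit absorbs the lapses into a higher α (0.30); the
4-parameter fit separates them and recovers the generating values. Freezing
the 4-parameter estimates and fitting each confidence model's criteria:

```r
dp_hat <- decision_params(fit4$params[1], fit4$params[2],
                          fit4$params[3], fit4$params[4])
for (m in confidence_models())
  print(fit_confidence(tab, design, dp_hat, m, mc_samples = 20000, seed = 7)$aic)
#> top2diff: 6096.289   bch: 6103.345   pe: 6324.939
```

The generating model (`top2diff`) attains the lowest AIC; `pe` is ruled out
by a wide margin. Cohort-level behavioural signatures:

```r
co <- simulate_cohort(15, design, model = "top2diff", seed = 3)
numerosity_effect(summarize_conditions(co$trials), design)
#>                    label  mean_diff        t df            p cohens_d
#> 1   numerosity: accuracy 0.01203704 1.571947 14 1.382836e-01 0.405875
#> 2 numerosity: confidence 0.14888889 8.063679 14 1.248572e-06 2.082033
```

Scaling all dot counts up at fixed ratios leaves accuracy almost unchanged
(d = 0.41, n.s.) but raises confidence strongly (d = 2.08) — the numerosity
effect, which only the top-two-difference computation reproduces at the
right magnitude.

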