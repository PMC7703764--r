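# ewcnet — edge-wise coupled non-homogeneous dynamic Bayesian networks

`ewcnet` learns time-varying regulatory networks from short multivariate time
series (gene expression, protein activity). It implements a non-homogeneous
dynamic Bayesian network (NH-DBN) in which a multiple-changepoint process
divides the series into segments with segment-specific interaction strengths,
and — the distinguishing feature — every individual edge carries a binary
indicator deciding whether its coefficient is **sequentially coupled** across
segments (its prior in segment *h+1* is centred on segment *h*'s posterior
expectation) or **uncoupled** (re-initialized at zero). The indicators are
inferred from the data, so the model finds a per-edge consensus between the
classic fully uncoupled and fully coupled NH-DBNs, and as a by-product labels
each edge as temporally stable ("coupled") or condition-sensitive
("uncoupled") — in a circadian-clock setting, for instance, a proxy for
light dependence.

## Model in brief

For one response node with covariate set $\pi$ and segments $h = 1..H$:

$$y_h \mid \beta_h, \sigma^2 \sim N(X_h \beta_h, \sigma^2 I), \qquad
\beta_1 \sim N(0, \sigma^2 \lambda_u I),$$
$$\beta_{h+1} \sim N\big(\delta \odot \tilde\beta_h,\;
\sigma^2 \mathrm{diag}\{\lambda_c \delta + \lambda_u (1-\delta)\}\big),$$

with $\tilde\beta_h$ the (fixed) posterior expectation of $\beta_h$,
$\delta_i \in \{0,1\}$ the per-coefficient coupling indicators,
$\sigma^{-2} \sim \mathrm{Gam}(a_\sigma, b_\sigma)$,
$\lambda_u^{-1} \sim \mathrm{Gam}(a_u, b_u)$,
$\lambda_c^{-1} \sim \mathrm{Gam}(a_c, b_c)$. Coefficients and noise variance
integrate out in closed form, and a Gibbs-within-RJMCMC sampler explores
covariate sets (fan-in ≤ 3, no self-loops), changepoints (even-order-statistics
prior, truncated Poisson(1) on the segment count), indicators and variance
parameters. Per-node posterior samples are merged into marginal edge
posterior probabilities; accuracy against a known network is summarized by
the precision-recall AUC. The homogeneous DBN (M1), fully uncoupled (M2),
fully coupled (M3), switch (M5) and segment-wise coupled (M6) models are
available as configuration-level variants sharing the same machinery, plus a
quadratic/interaction design transformation.

The package also ships the synthetic RAF-pathway benchmark generator
(11 nodes, 20 edges, 31 regression coefficients; 4 segments of 5 transitions;
four temporal coefficient types T1–T4; observational noise at signal-to-noise
ratio 3) and evaluation utilities (PR curves/AUC, Gelman–Rubin PSRF
monitoring, paired AUC-difference experiment driver).

## Worked example

Generate one benchmark dataset (scenario T1&T3 with K = 15 of 31 coefficients
truly coupled), infer the network with the changepoints fixed at the truth,
and evaluate:

```r
library(ewcnet)
sim <- simulateRafData(K = 15, scenario = "T1T3", m = 5, snr = 3, seed = 42)
fit <- inferNetwork(sim$data,
                    chainConfig(nIter = 5000, burnIn = 2500, thin = 10,
                                seed = 1, fixedTau = sim$tau))
pr <- precisionRecallAuc(fit, sim$truth)
cat(sprintf("PR-AUC: %.3f\n", pr$auc))
cat(sprintf("inferred coupled fraction: %.3f\n", inferredCoupledFraction(fit)))
head(labelEdges(fit, topK = 20), 8)
```

```
PR-AUC: 0.582
inferred coupled fraction: 0.508
  from   to score  pCoupled     label
1 Plcg PIP3 0.964 0.9460581   coupled
2  PKA  Jnk 0.892 0.8699552   coupled
3  PKA  Erk 0.792 0.8989899   coupled
4 PIP3 PIP2 0.656 0.8475610   coupled
5  PKA  P38 0.616 0.2077922 uncoupled
6  PKC  PKA 0.608 0.7960526   coupled
7  Erk  PKA 0.608 0.5723684       mix
8 PIP2  Mek 0.560 0.7857143   coupled
```

The PR-AUC of 0.58 is the area under the precision-recall curve against the
true 20-edge network (1 would be perfect ranking; the 0.17 edge density would
be chance). The inferred coupled fraction of 0.51 tracks the true fraction
15/31 ≈ 0.48, and the per-edge labels separate stable from time-varying
interactions via the 2:1 posterior-odds rule on the sampled indicators.

A command-line wrapper with `simulate`, `infer`, `evaluate` and `experiment`
subcommands is installed at `system.file("cli", "ewcnet", package = "ewcnet")`.

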