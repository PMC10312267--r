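# bdcfmri

Which fMRI dataset — a resting-state run or an active-task run — tells
us more about the effective connectivity of a neural network?
`bdcfmri` makes that question quantitative. It implements, in R with a
small C++ core, the full chain:

1. **Spectral dynamic causal modelling per subject.** Linear neural
   dynamics `dz/dt = A z + C u + v` with power-law endogenous
   fluctuations and a fixed canonical haemodynamic kernel are inverted
   against multivariate-autoregressive cross-spectral densities of the
   BOLD timeseries by variational Laplace (Gauss–Newton with
   Levenberg–Marquardt damping), yielding a Gaussian posterior over the
   coupling parameters and a free energy `F = accuracy − complexity`.
   Between-region couplings `A_ij` (Hz) carry the shrinkage prior
   `N(0, 1/64)`; self-connections are unitless log-scalings `s` of the
   default rate, `−0.5·exp(s)` Hz, with prior `N(0, 1/256)`.
2. **Hierarchical group summary.** After re-inverting every subject
   under grand-average priors pooled over both datasets, each dataset is
   summarised by a parametric-empirical-Bayes model
   `theta_s = X beta + e_s`, giving a Gaussian group belief
   `N(mu, Sigma)` over the invariant connectivity and a group free
   energy.
3. **Bayesian data comparison.** Three indices in nats per dataset:
   parameter certainty `−0.5 ln|2πe Sigma|`; information gain over
   parameters `KL(posterior ‖ prior)`; and information gain over models,
   the discrete KL divergence from a uniform prior over a leave-one-out
   model space (21 models for 5 regions) to the posterior implied by
   Bayesian model reduction. Differences are labelled on conventional
   evidence thresholds (1.1 / 3 / 5 nats).

Because the motivating data are access-restricted, the package ships a
fully tested synthetic generator that emulates the paired design: the
same subjects "scanned" at rest and under a block-design social-cognition
style task (TR 0.72 s, 207 s runs, 5 regions, input driving region 5,
task coupling twice rest, matched noise), with ground-truth graphs
retained for recovery checks.

Audience: methods researchers and imaging groups who want to benchmark
acquisition conditions (task vs rest, denoising choices, run lengths) by
the information the resulting data provide about model parameters,
rather than by signal-to-noise ratio alone.

## Worked example

```r
library(bdcfmri)

cfg <- pipeline_config(simulation = sim_config(n_subjects = 8, seed = 42),
                       seed = 42)
res <- run_pipeline(cfg, write_artifacts = FALSE)
res$report
```

On one machine this printed:

```
<quality_report>
Per-dataset indices (nats):
 dataset parameter_certainty info_gain_parameters info_gain_models
    rest            37.38707             59.67198        0.3051244
    task            36.18222             50.04319        0.5751879
Differences relative to the worst dataset:
                index best_dataset difference_nats     evidence
  parameter_certainty         rest       1.2048518     positive
 info_gain_parameters         rest       9.6287915  very strong
     info_gain_models         task       0.2700635 insufficient
```

Reading it: the two datasets pin the 25 invariant-connectivity
parameters about equally tightly (certainty difference just over the
1.1-nat positive-evidence threshold), model discrimination is weak for
both (hard-to-distinguish architectures, as intended), and the parameter
information gain differs decisively. At this desk scale the total gain
is dominated by self-connection displacement rather than by the
between-region coupling contrast, which here favours the task dataset —
the decomposition printed by `analysis/04_compare_datasets.R` separates
the two blocks; see the methods vignette for why, and for what does and
does not generalise to real data.

The numbered scripts under `analysis/` run the same experiment as a
staged workflow (simulate → subject fits → group inference → comparison)
at n = 20, writing TSV/JSON datasets, CSV parameter tables and a JSON
quality report under `results/`.

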