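# thoughtprobe

An R package for studying the electrophysiological signatures of ongoing
thought with multi-dimensional experience sampling (MDES). It provides, end
to end:

- a **synthetic cohort generator** with known ground truth: 32-channel EEG
  with 1/f background, narrowband oscillators, and planted band-power
  effects tied to latent thought states that also drive 7-point Likert
  probe reports on seven dimensions (`off_task`, `freely_moving`, `sticky`,
  `goal_directed`, `internal`, `self`, `other`);
- **preprocessing** (1-55 Hz band-pass, 60/120 Hz notch, 2-s epochs with
  1-s context, common average reference) and **spectral features**: Welch
  power on a 4-30 Hz / 1 Hz grid with the aperiodic (1/f) component
  removed by a robust log-log line fit, giving a 32 x 27 periodic matrix
  per epoch;
- **group statistics**: dependent-samples cluster-based permutation tests
  over the electrode x frequency grid, linear mixed-model controls with
  participant/session random intercepts and correlated-dimension rating
  covariates, and task-rest spectral similarity;
- **decoding**: a shallow 1-D CNN (8187 parameters, implemented in base R
  with exact backpropagation), SMOTE class balancing, within-participant
  cross-validation, leave-one-subject-out transfer learning with a leakage
  audit, and label-permutation significance testing;
- a **file-based workbench**: an EDF 16-bit codec, CSV/JSON artifacts for
  every stage, and a staged command-line pipeline
  (`inst/cli/thoughtprobe.R`).

Defaults everywhere mirror the emulated study protocol (7 participants x 7
sessions, ~80-minute sessions, 35 probes at 90-150 s gaps, two 5-minute
rest blocks, 256 Hz). The examples below run reduced sizes so they finish
in minutes. See `vignettes/methods.Rmd` for the modelling assumptions and
the reasoning behind the numerical choices.

## Worked example

Simulate a small cohort with planted off-task effects, test for
electrode-frequency clusters, verify the effect with a mixed model, and
decode the dimension from single trials:

```r
library(thoughtprobe)

cfg <- synth_config(n_participants = 3, n_sessions = 2, n_probes = 12,
                    probe_gap = c(20, 30), task_duration = 400,
                    effects = default_effects(gain = 0.8), seed = 7)
cohort <- simulate_cohort(cfg, include_rest = FALSE)

task <- cohort_task_trials(cohort, window_s = 12)   # preprocess + features
trials <- do.call(bind_trials, task)
length(trials$matrices)
#> [1] 360
table(trials$labels[, "off_task"])
#> discarded     lower     upper
#>        95       120       145
```

Each probe contributes six 2-s trials (the 12-s pre-probe window); ratings
of 4 are discarded, 1-3 are `lower`, 5-7 are `upper`.

```r
pairs <- Filter(Negate(is.null),
                lapply(task, session_condition_pairs, "off_task"))
clu <- cluster_permutation_test(lapply(pairs, function(p) p$upper$matrix),
                                lapply(pairs, function(p) p$lower$matrix),
                                n_perm = 500, seed = 11)
ps <- sapply(clu$clusters, `[[`, "p")
c(significant = sum(ps < 0.05), min_p = min(ps))
#> significant       min_p
#>      1.0000      0.0439

mask <- cluster_mask(clu)            # 77 cells in the significant cluster
fit <- fit_lmm_end(lmm_response_table(pairs, mask))
fit
#> <lmm_result> end effect = 0.2689 (SE 0.0447), LRT p = 0.0001374 [singular fit]
round(lmm_end_ci(fit), 3)
#> [1] 0.181 0.356
```

The permutation test finds one significant posterior alpha-band cluster and
the mixed model (`response ~ end + (1 | participant) +
(1 | participant:session)`) confirms the upper-vs-lower difference. The
singular-fit flag is expected at this tiny scale (a variance component hits
zero) and is reported rather than raised.

```r
scfg <- scnn_config(learning_rate = 3e-3, max_epochs = 25, patience = 25)
res <- within_participant_cv(trials, "off_task", config = scfg,
                             n_iterations = 2, seed = 1,
                             min_class_trials = 25)
round(res$mean, 3)
#>   mcc   auc    ba
#> 0.176 0.649 0.587
```

Above-chance but modest single-trial decoding is the realistic outcome at
this cohort size; `permutation_significance()` quantifies it against
label-shuffled runs, and `loso_transfer_cv()` evaluates cross-participant
generalization with a small adaptation set.

## The staged pipeline

The same analysis can be run stage by stage on disk, with EDF recordings
and CSV/JSON artifacts:

```r
cfg <- run_config(synth = list(n_participants = 2, n_sessions = 2,
                               n_probes = 8, probe_gap = c(16, 20),
                               task_duration = 160, seed = 42),
                  seed = 42)
cli_run("all", cfg, "runs/demo")   # or each stage: simulate, features,
                                   # label, cluster-test, lmm, similarity,
                                   # classify, report
```

or from a shell:

```sh
Rscript inst/cli/thoughtprobe.R --config my_run.json --out runs/demo all
```

`runs/demo/report.md` summarizes every stage, including the overlap of
detected clusters with the generator's ground-truth masks.

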