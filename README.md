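# rmdor

Restricted mean duration of response (DOR) estimation and inference for
randomized phase 2 screening trials in oncology, with a multi-state
synthetic trial generator and a resampling simulator of trial operating
characteristics.

## The problem

Phase 2 oncology trials decide whether a phase 3 trial is worth running.
The usual early endpoints both have blind spots: the objective response
rate (ORR) ignores how long responses last, and progression-free survival
(PFS) comparisons (log-rank, median, restricted mean) fail exactly where
immunotherapy is interesting — delayed but durable responses that make the
survival curves cross. Classical DOR analyses condition on responding,
which breaks randomization.

The restricted mean DOR repairs this: the expected time spent in objective
response (CR or PR) up to a horizon τ, averaged over **all** randomized
patients. With S_PFS the Kaplan–Meier (KM) curve of PFS and S₀ the KM
curve of the composite "first response or progression/death" time,

    DOR(τ) = ∫₀^τ { S_PFS(t) − S₀(t) } dt,

the area between two KM curves; the integrand is the probability of being
in response (PBIR) at t. Substituting first CR for first response and
differencing the areas partitions restricted mean PFS, in the partitioned
survival (Q-TWiST) fashion, into durations of complete response (DOCR),
partial response (DOPR) and stable disease (DOSD):

    RMST_PFS = DOCR + DOPR + DOSD,   DOR = DOCR + DOPR.

The package implements the estimators, ratio effects with stratified
bootstrap CIs and permutation p-values (testing the difference, which is
well defined even when a resample has no responders), the four-test phase 2
battery (log-rank PFS, χ² ORR, RMST ratio of PFS, restricted mean duration
ratios), a multi-state cohort generator with presets for three
decision-making regimes, and a trial simulator that tabulates power and
type I error.

## Worked example

Four uncensored patients: A responds (PR) at month 2 and progresses at 10;
B responds at 2, converts to CR at 4, progresses at 12; C and D never
respond, progressing at 3 and 6.

```r
library(rmdor)
x <- cohort(patient_id = c("A", "B", "C", "D"), arm = "arm1",
            t_response = c(2, 2, NA, NA),
            first_response_type = c("PR", "PR", NA, NA),
            t_cr = c(NA, 4, NA, NA),
            t_event = c(10, 12, 3, 6), pfs_event = 1)
rm_partition(x, tau = 12)
#> Restricted mean PFS partition up to tau=12 months (effective 12)
#>   RMST_PFS  7.7500 months
#>   DOR       4.5000 months
#>   DOCR      2.0000 months
#>   DOPR      2.5000 months
#>   DOSD      3.2500 months
```

With no censoring these are just average truncated times-in-state: mean
PFS (10+12+3+6)/4 = 7.75 months, of which on average 4.5 months were spent
in response (2.0 in CR: patient B's months 4–12, averaged over everyone)
and 3.25 progression-free before response.

A simulated crossing-hazards trial (scenario II preset: ORR 21% vs 11%,
median PFS 2.1 vs 3.3 months, curves crossing mid follow-up), censored the
way a 100-patient-per-arm phase 2 trial would be:

```r
trial <- simulate_cohort("scenarioII", n_per_arm = 100, seed = 7)
trial12 <- apply_admin_censoring(trial, tau = 12, seed = 8)
set.seed(9)
run_battery(trial12, taus = 12,
            tests = c("LOGRANK_PFS", "CHISQ_ORR", "RMST_PFS", "DOR"),
            n_boot = 1000, n_perm = 1000, tau_context = 12)
#>          test  tau estimate  ci_low ci_high p_value      method degenerate
#> 1 LOGRANK_PFS 12.0       NA      NA      NA   0.763  asymptotic      FALSE
#> 2   CHISQ_ORR 12.0     0.04 -0.0531   0.133   0.400  asymptotic      FALSE
#> 3    RMST_PFS 11.2     1.13  0.8724   1.457   0.360  asymptotic      FALSE
#> 4         DOR 11.2     5.41  2.0527  22.385   0.005 permutation      FALSE
```

The marginal PFS tests (log-rank p = 0.76, RMST ratio p = 0.36) and the
ORR χ² (p = 0.40) see nothing, but the active arm's responses last over
five times longer in restricted mean (ratio 5.41, permutation p = 0.005):
the duration endpoint recovers the signal the others miss. Horizons are
truncated to the shorter arm's follow-up (here 11.2 months), mirroring
standard restricted-mean practice.

Operating characteristics over thousands of simulated trials:

```r
cfg <- simulation_config("scenarioII", n_per_arm = 100, n_replicates = 5000,
                         taus = c(6, 9, 12), alphas = c(.05, .10), seed = 1)
operating_characteristics(cfg)
```

A thin command-line wrapper ships in `inst/cli/rmdor` with subcommands
`estimate`, `simulate-oc` and `make-synthetic`; each run writes its
outputs next to a JSON manifest (resolved configuration, seed, tool
version) sufficient to reproduce them.

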