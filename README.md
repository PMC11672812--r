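# pandagrowth

Lifespan weight-for-age modelling for captive giant pandas
(*Ailuropoda melanoleuca*).

Body weight is the most accessible health indicator for a species whose
newborns weigh ~0.1% of their mothers and whose adults can be dangerous to
handle. Zoo weighing records, however, are irregular in time and biased by
feeding status: an adult weighed after its bamboo ration reads 15–20 kg
heavier than the same animal fasted. `pandagrowth` turns such longitudinal
records (`animal_id, sex, birth_date, measure_date, weight_kg`) into a
day-by-day weight-for-age reference chart with bootstrap 95% confidence
bands, for keepers and veterinarians who need to judge whether a given
panda's weight is healthy for its age and sex.

The pipeline:

1. **Validate and label** records: age in days, age groups (newborn 0–30 d,
   cub 31–500 d, sub-adult/adult 501+ d), natural seasons and
   reproductive periods, adult window 66–246 months.
2. **Calibrate for feeding status**: per sex, fit a Gompertz sub-adult
   growth curve *w(t) = A·exp(−b·exp(−kt))*, adjust each animal's weights
   within a calendar month to the month's mean record day along the curve,
   split each month of age into two k-means clusters (empty vs non-empty
   stomach) and delete the higher cluster. The mean distance between paired
   cluster centers estimates the meal mass.
3. **Model growth** per age group: weight ~ (sex, age in days) with five
   tree-ensemble regressors compared by 5-fold CV on a 3:1 split, and a
   300,000-combination hyperparameter grid (subsampled by default) for the
   gradient-boosted model.
4. **Chart**: retrain the tuned model on B bootstrap subsets (one-fifth of
   the data each, drawn with replacement, scored out-of-bag) and summarise
   each day of age by the median prediction and percentile 2.5/97.5 band.
5. **Statistics**: two-sided Mann–Whitney comparisons of adult weight
   across seasons, reproductive periods and sexes, and growth-velocity
   estimates from adjacent records and from consecutive chart days.

Since institutional breeding records are not redistributable, the package
includes a synthetic-cohort simulator (`sim_config()`, `simulate_cohort()`)
with known ground truth — growth curves, feeding labels, seasonal dip —
against which the whole pipeline is tested.

## Worked example

```r
library(pandagrowth)

cfg <- sim_config(n_female = 40, n_male = 40, fed_fraction = 0.5,
                  min_followup_days = 2500, seed = 1)
rs  <- simulate_cohort(cfg)$records        # 11,717 records
cal <- calibrate_records(rs, seed = 1)
print(cal$report)
#> Feeding-status calibration report
#>   female: cluster distance 16.3 +/- 2.8 kg over 321 age-months; removed 1887 / kept 1908 (60 months skipped)
#>   male: cluster distance 20.0 +/- 3.0 kg over 325 age-months; removed 1881 / kept 1820 (35 months skipped)
#>   total: 11717 records in, 3768 removed, 7949 kept
```

The simulator drew fed-state offsets of 16.5 kg (female) and 19.9 kg
(male); the calibration recovers them as the cluster-center distances and
removes the fed weighings. Adult medians after calibration:

```r
adults <- filter_adults(cal$records)
median(adults$weight_kg[adults$sex == "female"])  #> 101.4 kg
median(adults$weight_kg[adults$sex == "male"])    #> 113.1 kg
```

Build the chart (B = 1000 for production use; 50 here for speed):

```r
ch <- weight_chart(cal$records, default_group_specs(), B = 50,
                   max_age_days = c(female = 3000, male = 3000), seed = 1)
ch[ch$age_day %in% c(0, 100, 1000, 3000) & ch$sex == "female", ]
#>        sex age_day  mean_kg median_kg ci_low_kg ci_high_kg    sd_kg n_replicates
#>     female       0   0.1509    0.1503    0.1447     0.1586 0.003608           50
#>     female     100   2.1377    2.1402    1.9639     2.2414 0.074525           50
#>     female    1000  97.3366   97.0241   95.8529    99.8843 1.145372           50
#>     female   3000 101.4860  101.4777  100.0355   102.8634 0.770273           50
```

Each row is the chart's reference entry for that day of age: the expected
weight (median across bootstrap replicates) and the 95% band capturing
model variability. `run_pipeline(run_config(...))` runs every stage and
writes CSV/JSON artifacts plus a manifest; a thin command-line front end
with `simulate`/`calibrate`/`train`/`chart`/`stats`/`run-all` subcommands
lives at `inst/cli/pandagrowth.R`.

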