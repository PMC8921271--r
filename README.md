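# bnetr

Specific radiation damage — metal reduction, disulfide cleavage and above
all aspartate/glutamate decarboxylation — accumulates in protein crystals
during X-ray data collection and silently distorts the deposited models,
because damaged side chains are almost always refined at full occupancy
and standard validation metrics do not look for the resulting local
B-factor inflation. `bnetr` is for crystallographers and structural
bioinformaticians who want to screen their own or others' structures for
these artefacts from the coordinate file alone.

## The metrics

**B_Damage** normalises each atom's isotropic B-factor against its local
crystalline environment. With the *packing density* of atom *j* defined as
the number of non-hydrogen atoms within 7 Å of it in the full crystal
lattice (symmetry mates and lattice translations included),

```
B_Damage_j = B_j / mean(B_i : atoms i in a similar packing-density environment)
```

where "similar environment" is the contiguous window of
`max(11, round(0.02 N))` atoms centred on *j*'s packing-density rank.
Values well above 1 flag candidate damage sites.

**B_net** summarises a whole structure. Taking the B_Damage values of the
Asp/Glu side-chain carboxyl oxygens (OD1/OD2, OE1/OE2), a Gaussian KDE
with Scott bandwidth `h = sd(v) · n^(−1/5)` is evaluated on 100 points
spanning `[min − 3h, max + 3h]`, and the 99-trapezium area is split at the
median B_Damage of *all* atoms in the structure (the median-containing
trapezium counts below):

```
B_net = B / A       (B: area above the median, A: area below)
```

An undamaged structure scores ≈ 1; damage pushes oxygen sites right of
the median and the score rises. A B_net above 3.0, or a cohort
**B_net-percentile** (rank among the 1000 structures nearest in
resolution) above 0.95, merits inspection.

The package also provides the cohort machinery: eligibility screening
(cryo-temperature 80–120 K, resolution ≤ 3.5 Å, R_free ≤ 0.4, per-atom
B-factors, full-occupancy Asp/Glu, ≥ 20 carboxyl oxygens, no nucleic
acids), least-squares dose-response fits with plateau exclusion, relative-SD
fit-consistency summaries, Spearman correlation scans, and a deterministic
synthetic-crystal generator so everything is testable offline.

## Worked example

```r
library(bnetr)

# a synthetic crystal with realistic Asp/Glu dilution, half of whose
# carboxyl oxygens carry a 2x B-factor inflation
cond  <- damage_series_conditions(seed = 1)
spec  <- cond$spec
spec$damage_factor <- 2
model <- generate_fixture(spec)

report <- compute_bnet_for_structure(model)
report
#> <structure_report> SYNT: B_net = 2.64, B_net(Asn/Gln) = 0.846
glance(report)
#> # A tibble: 1 x 12
#>    bnet area_below area_above median_all bandwidth n_selected selection_mode ...
#> 1  2.64      0.275      0.725      0.991     0.220         56 asp_glu
```

The damaged structure scores B_net = 2.64: 72.5 % of the carboxyl-oxygen
KDE mass sits above the all-atom median B_Damage (0.991), against 27.5 %
below. The Asn/Gln control — amide oxygens, which do not decarboxylate —
stays near 1 (0.846), as it should. A five-point dose series from the same
crystal shows the dose response the metric is designed for:

```r
series <- generate_damage_series(cond$spec, cond$doses, slope = cond$slope)
bnets  <- vapply(series, function(m) compute_bnet_for_structure(m)$bnet$bnet, numeric(1))
round(bnets, 3)
#> [1] 1.028 1.319 1.355 2.162 2.626
fit_dose_series(data.frame(dose = cond$doses, bnet = bnets))
#> <dose_series_fit> series: gradient 0.1649 /MGy, intercept 1.013, R^2 0.958 (n = 5)
```

B_net rises strictly with dose from its null value ≈ 1, with a positive
fitted gradient near the series' designed 0.2 MGy⁻¹. `autoplot()` on a
`bnet_result` draws the KDE with the median split shaded;
`tidy()` returns the curve.

For shell use, `exec/bnet` wraps the same functions
(`single`, `cohort`, `fixture`, `series` subcommands; exit code 0 on
success, 2 for an ineligible structure, 1 on error).

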