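---
title: "Simulating a Merino breeding program with genotype-by-environment interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a Merino breeding program with genotype-by-environment interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(merinosim)
```

## The question the simulator answers

German Merino lambs are increasingly fattened on pasture, but the routine
progeny testing that feeds the genetic evaluation happens indoors at test
stations. When the same trait expressed on pasture and indoors behaves as
two genetically correlated traits (genotype-by-environment interaction,
G×E), selecting on station records alone loses gain in the production
environment. `merinosim` is a forward-in-time stochastic simulator of a
closed herdbook breeding program built to quantify that loss and to compare
three progeny-testing designs: station testing only (`ST`, the reference),
field testing only (`FT`), and both (`ST_FT`).

## Model components

### Genomes and inheritance

Founders carry phased biallelic haplotypes on a configurable genome map.
The default map — 26 autosomes × 1 Morgan × 200 evenly spaced loci (5,200
loci) — is a deliberate desk-scale stand-in for a 50k ovine SNP chip: dense
enough to sample 1,000 QTL and to make linkage real, small enough that a
three-scenario study runs on one desktop core. Founder allele frequencies
are uniform on [0.05, 0.5] (a typical post-QC chip MAF profile) and
founders start in linkage equilibrium; five generations of random mating
(`burn_in_random_mating()`) then build the relatedness, linkage
disequilibrium and pedigree structure the breeding program starts from.

Meiosis (`make_gametes()`) follows the Haldane model: Poisson crossover
counts per chromosome (mean = map length in Morgan), uniform crossover
positions, no interference, random start haplotype — the standard choice
of forward simulators in this field.

### Trait architecture

Nineteen traits (reproduction, conformation, field and station fattening,
carcass, feed conversion) share 1,000 purely additive QTL drawn uniformly
from the panel. Each QTL receives one effect per trait from a multivariate
Gaussian whose correlation matrix is the target genetic correlation matrix,
so pleiotropy — not linkage — carries the trait correlations; under linkage
equilibrium the per-locus effect correlation equals the TBV correlation.
G×E is expressed as a genetic correlation of 0.8 between the field and
station versions of ADG, FLN, UMD and UFD — the level usually quoted as
the threshold at which re-ranking across environments becomes a practical
concern.

All other off-diagonal correlations default to zero. This is an explicit,
overridable default, not a claim about Merino genetics: the full
literature-compiled 19×19 correlation matrix a routine evaluation carries
is not publicly deposited, so the package ships only the entries that are
publicly stated (the four 0.8 cross-environment values) and accepts a
complete matrix via `trait_correlations(custom = )` or the YAML config.
Two consequences are worth knowing. First, a compiled matrix is typically
indefinite; `project_to_psd()` implements the standard repair (clip
negative eigenvalues, reconstruct, rescale to unit diagonal). Second, the
sparser default correlation structure means lamb-stage EBVs draw on less
auxiliary information than a fully parameterized evaluation would supply,
which depresses per-cycle genetic gain somewhat (see "Known
limitations").

True breeding values are standardized once, on the initial breeding
population produced by the burn-in, to mean 100 and genetic variance 10
per trait; the standardizers are then frozen so that genetic trend and
variance are measured on a single scale for the whole run. Phenotypes add
an independent Gaussian residual with variance `10·(1−h²)/h²`; residuals
are uncorrelated across traits (no reliable residual-correlation
estimates exist for this panel) and no
permanent-environment effect is modelled, since no trait is recorded twice
on the same animal.

### The breeding program

One cycle is one year. Within a cycle the order is fixed: mate → record →
evaluate → select (entry) → exits/retention → refill. 469 breeding rams
and 7,185 breeding ewes (scalable) are mated with ewes split randomly into
near-equal harems; litter sizes are 1/2/3 with probabilities
0.56/0.40/0.04 and lambs die before day 42 with probability 0.1. These
litter probabilities imply 1.48 lambs born per ewe and lambing; breeding
managers for this population quote an average of 1.8, which the
probabilities cannot produce. The probabilities are the generative rule
here; both are exposed in the configuration.

Selection acts on a total merit index (TMI), a fixed weighted sum of EBVs
whose weights sum to 100; the station fattening traits carry zero weight —
they are recorded to support the evaluation, and how much of that support
reaches their field counterparts is governed by the evaluation's parameter
matrix (see "Evaluation"). Entry selection takes the best males amounting to 2%
of the surviving lamb crop (licensing; a further 10% of presented males
are rejected at random) and the best females amounting to 20% of the crop
(herdbook registration). The fractions are read as fractions of the whole
crop — every lamb of either sex is an eligible selection candidate —
because that reading balances the replacement flow at the default cohort
sizes:
licensed males (~172/year full scale) almost exactly replace the rams the
default survival schedule removes (~178/year), and registered females
oversupply the ewe flock so the refill step truncates them by TMI, which
is where the program's second selection timepoint has real intensity.
Reading the gates as fractions of each sex alone starves the cohorts and
collapses the population exponentially — a structurally inconsistent
program.

Exits are stochastic with age- and sex-specific retention (defaults: rams
0.65/year through age 6, ewes 0.80/year through age 8, then forced exit) —
the geometric-style pattern of real culling records; the schedule is a
calibration knob and fully overridable. Retention among survivors is by
TMI truncation whenever survivors exceed the open slots. Both compositions
of "probabilistic leaving" with "TMI selection at the second timepoint"
were prototyped; making the TMI choose *who* leaves (survival draws only
setting the count) rejuvenates the ram cohort and collapses its EBV
accuracy far below what progeny-tested ram cohorts achieve in practice,
so the package keeps exits random and lets truncation bind only on
oversupply.

### Recording and scenarios

Every surviving lamb is scored for wool, muscle and body conformation
before the evaluation runs, ewes get a litter-size record at first
lambing, and a random 25% of the lamb crop is scored for nursing ability.
Progeny testing draws male lambs per sire — 8 for station, 20 for field.
These group sizes exceed the male progeny a sire typically has
(about 10–12 at the configured cohort sizes and litter distribution), so
the groups are drawn independently and may overlap: in the combined
scheme essentially every son is recorded in both environments, which is
the only reading under which the combined scheme carries at least as much
field information as field-only testing — a property the design plainly
intends. A strict-disjoint mode (`ft_disjoint = TRUE`) is available for
designs where one lamb cannot be tested in both environments. Sires with
fewer eligible sons contribute all of them and the shortfall is logged.
Tested lambs are drawn before selection, so a later-licensed ram may carry
own fattening records; fattening and carcass records are only ever created
through this birth-cycle progeny-test draw, never as own-performance
records at later life stages.

### Evaluation

EBVs come from a multi-trait pedigree BLUP animal model: per-trait means
as the only fixed effects, animal effects with covariance `A ⊗ G0`,
diagonal residuals, no REML. The parameter matrix behind `G0` is *not*
the simulation truth: `G0 = 10·C_eval`, where `C_eval` defaults to the
true correlation matrix with every field–station correlation set to zero
(`evaluation_correlations()`). This models a routine evaluation that has
no established cross-environment parameters — the field fattening traits
are recent additions to the index and the evaluation treats them as
separate, unlinked traits. The distinction is the crux of the G×E
penalty: the simulated genetics correlate field and station performance
at 0.8, but the evaluation cannot exploit station records to predict
field merit, so a station-only scheme leaves the field traits
essentially unevaluated (with the default background correlations their
EBVs are exactly zero and their accuracy is undefined/NA). An evaluation
with full knowledge of the cross-environment correlations can be studied
by passing `C_eval = C`; it largely erases the gap between station-only
and combined testing, which is the theoretically expected ~20%-loss
regime rather than the collapse regime. Records are restricted to animals
born in
the last three cycles and the pedigree is traced seven generations up from
them, with truncated parents coded unknown — the usual shape of routine
evaluations. `A⁻¹` is built sparsely by Henderson's rules with
Mendelian-sampling variances from Meuwissen–Luo inbreeding coefficients.

The solver is preconditioned conjugate gradients with a per-animal
block-Jacobi preconditioner; a direct dense solve is used automatically
when the system is small (`n_animals × n_traits ≤ 4000` — a bound on
unknowns rather than on animals, since 19 traits make even 500 animals a
9,500-unknown dense system) and doubles as the test oracle. The exported
default tolerance is a relative residual of 1e-8; the scenario engine runs
its per-cycle evaluations at 1e-6, which changes EBV–TBV correlations by
far less than replicate noise while saving a third of the iterations.
Inbreeding coefficients are cached incrementally along the append-only
pedigree and reused across evaluations.

## Study design and scale

The desk profile — `study_config()` — runs each scenario at `scale_factor
0.1` (47 rams, 719 ewes, 79 founders; ceiling rounding) with 10 replicates
of 20 cycles, which keeps a full three-scenario sweep around a quarter of
an hour on one core. Scaling multiplies all cohort sizes together, so
selected fractions and with them selection intensity are preserved. The
full-size profile (`study_config("full")`: scale 1, 50 replicates) is the
real study design and runs for hours.

Replicates are paired across scenarios by common random numbers: founder
genomes, burn-in and QTL architecture come from a per-replicate stream
shared by all scenarios, and the cycle phase then diverges with the
recording scheme. Paired t tests over replicate statistics are therefore
well defined. Cycles 1–9 are demographic burn-in; genetic gain is scaled
to zero at cycle 10 and expressed in units of the cycle-10 genetic
standard deviation of the breeding population, and EBV accuracies are
averaged over evaluated cycles 11–20 within replicate before averaging
across replicates.

## What the synthetic data does and does not emulate

The generator reproduces the mechanisms that drive the design question:
Mendelian inheritance with linkage, pleiotropic trait correlations
including G×E, information flow through a pedigree BLUP, and
overlapping-generation selection dynamics. It does not reproduce a real
chip-genotyped founder panel (no such panel is publicly deposited for
this population), real linkage disequilibrium or MAF spectra, the full
literature-compiled correlation matrix, maternal effects, or
non-additive gene action. Passing tests therefore show that
the program logic and the estimation machinery behave correctly and that
scenario contrasts point the right way — not that absolute gains transfer
to any real flock.

Two desk-scale artifacts deserve explicit mention:

* **Genetic drift and kinship scale like 1/N.** At one tenth of the real
  population size, inbreeding accumulates roughly ten times faster. Mean
  kinship of the desk-scale breeding population (founders as the
  zero-kinship base) sits near 0.06–0.07 at the reference cycle and climbs
  ~0.006–0.008 per cycle — linear in cycle, but an order of magnitude
  above what the same program produces at full size; only a full-size run
  shows full-size kinship levels.
* **Per-cycle gain depends on the correlation structure supplied.** With
  the default (sparse) correlation matrix, lamb-stage TMI accuracy — the
  driver of the male path — lacks the auxiliary correlated-trait
  information a fully parameterized evaluation would add, and the
  simulated trend settles near 0.29–0.31 genetic SD per cycle; richer
  correlation matrices push it upward. Scenario orderings and relative
  contrasts are robust to this.

## Numerical choices

* PSD projection tolerance: eigenvalues clipped at exactly zero; outputs
  accepted with minimum eigenvalue ≥ −1e-10; the projection is idempotent
  to the same tolerance.
* Ties in truncation selection are broken by a seeded uniform draw, so
  selection among identical index values is exchangeable and reproducible.
* `select_top()` selects `ceiling(fraction · n)` candidates; cohort refill
  truncates new entrants by TMI when oversupplied and logs shortfalls
  otherwise (the cohort then runs short — the default schedule is close to
  flow-balanced, so shortfalls are small and transient).
* Unknown parents form a single genetic group with mean zero; no
  genetic-group effects.
* All randomness — including inside the compiled meiosis and solver code —
  flows through R's RNG, so a master seed makes entire studies bit
  reproducible; per-replicate streams are derived by a counter scheme so
  adding replicates never perturbs existing ones.

## Known limitations

Beyond the desk-scale artifacts above: the TMI weights are taken as given
(no economic-weight derivation or index optimization); genomic selection
is out of scope (pedigree BLUP only); rams are not transferred to
production herds; no preselection on subjective judgement is modelled; and
the real program's observed age-specific culling rates are approximated by
the geometric defaults described here.

## A worked micro-example

```{r}
library(merinosim)

cfg <- study_config(seed = 1)          # desk profile: scale 0.1, 10 reps
study <- run_study(cfg)                # ~15 min on one core

gain_table(study)                      # gain per scenario and cycle
accuracy_table(study)                  # accuracy per scenario/cohort/trait
compare_scenarios(study)               # paired t tests + letter display
autoplot(study)                        # gain trajectories
```
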