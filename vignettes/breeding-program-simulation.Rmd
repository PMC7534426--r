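---
title: "Simulating genomic and phenotypic selection in ryegrass breeding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating genomic and phenotypic selection in ryegrass breeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ryegrassGS)
```

## The problem

Perennial ryegrass (*Lolium perenne* L.) is an outbreeding, self-incompatible
forage grass bred as synthetic varieties: full-sib families are evaluated as
plot pools, the best single plants are polycrossed in small parent groups,
and the resulting synthetics are again evaluated as plots. A breeding cycle
takes about 12 years, and key traits can only be phenotyped on multi-plant
plots. Genomic selection (GS) promises both higher selection accuracy (plants
can be ranked on genomic estimated breeding values, GEBVs, instead of being
picked at random from good families) and shorter effective cycle times
(material from a previous cycle can be recruited as soon as it exists, rather
than after it has been phenotyped).

`ryegrassGS` is a stochastic, gene-level simulator of this system. It
simulates founder genomes by gene dropping through a long historical
population, lays a multi-trait pleiotropic QTL architecture over them, runs
overlapping 12-year breeding cycles under five scenarios (two phenotypic, three
genomic), and reports cumulative genetic gain, selection accuracies, the
additive-variance trajectory, linkage disequilibrium (LD) and
heterozygosity.

## Founder genomes

The genome is 7 chromosomes of 100 cM. Each meiosis draws a
Poisson(\(\lambda = 1\)) number of crossovers per chromosome, placed uniformly
on the map with no interference; positions are continuous cM, so a map
function is never discretized. An oversampled pool of 2500 bi-allelic loci
per chromosome (2.27 times the 1100 finally needed) starts from uniform
(0, 1) allele frequencies and is dropped through 2000 generations of random
mating with replacement: 1000 generations at size 2000, then a linear decline
to 1000. The decline is linear interpolation; among "gradual decrease"
schedules, nothing sharper is identifiable from the outputs.
A symmetric allele-flip mutation at \(2.5 \times 10^{-5}\) per locus per
transmitted gamete operates during the historical phase only; the breeding
phase is mutation-free.

From the final generation, 1000 SNPs and 100 QTL per chromosome are drawn at
random among loci with minor allele frequency above 0.05; SNP and QTL sets
are disjoint. Twenty initial varieties are then formed by sampling 200
plants (without replacement within a variety, independently across
varieties, since \(20 \times 200\) exceeds the 1000 founders) and random
mating each sample for one generation with distinct parent pairs.

The historical phase is monoecious with selfing possible — a neutral
Wright–Fisher-style choice; self-incompatibility is enforced everywhere in
the breeding phase, where it matters for the mating design.

These choices give emergent founder statistics close to empirical ryegrass
panels: observed SNP heterozygosity near 0.34 and mean adjacent-SNP
\(r^2\) near 0.2 within varieties, with \(r^2\) decaying steeply over the
first few cM (compare `ldDecay()` with `expectedR2Sved()`; recombination
fractions use Haldane's map function).

## Trait architecture and phenotypes

Four traits share all 700 QTL (full pleiotropy). Allele substitution effects
are drawn from a zero-mean multivariate normal with unit per-trait variance
and an effect correlation of 0.7 between traits 3 and 4 (all other pairs 0),
so the realized genetic correlation between traits 3 and 4 is 0.7.
True breeding values (TBVs) are additive sums of dosage times effect; the
TBV of a plot is the mean TBV of its member plants.

Plot heritability is defined as the squared correlation between plot TBV and
plot phenotype. Rather than tuning effect sizes by trial and error, the
package solves the calibration in one deterministic step: on a calibration
set of F2-style plots built from the initial varieties,
\[
\sigma^2_{e,t} = \mathrm{var}(\text{plot TBV}_t)\,\frac{1 - h^2_t}{h^2_t},
\]
per trait, with targets \(h^2 = (0.3, 0.6, 0.4, 0.2)\). This leaves effect
correlations untouched (correlation is scale-invariant) and reproduces the
targets on independent plot samples to within sampling error. Plot
phenotypes are plot TBV plus an independent \(N(0, \sigma^2_e)\) deviate per
trait; single-plant phenotypes (used only to group polycross parents by
heading date, trait 2) use the same calibrated variance. Phenotypic variance
is not fixed globally; it emerges as \(\mathrm{var}(\text{plot TBV}) +
\sigma^2_e\).

## One breeding cycle

Each cycle runs on a fixed 12-year calendar (`eventCalendar()`):

* **Year c** — 250 F1 families of 40 are created; each family crosses one
  random plant from each of two distinct varieties (or recruited parents in
  later cycles).
* **Year c+3** — F1 families are intermated into F2 plots of 40 (distinct
  parent pairs, no selfing); plots are phenotyped, and in genomic scenarios
  genotyped as the mean allele dosage of 20 sampled plants (a sampled allele
  frequency of 0.7 gives dosage 1.4).
* **Year c+4** — the 50 best F2 families are kept by a selection index over
  traits 1, 3 and 4 (phenotypic or GEBV-based); greenhouse single plants
  (40 per kept family) are grown, 400 polycross parents are chosen (at
  random per family in phenotypic scenarios, by GEBV index in genomic ones),
  grouped into 50 groups of 8 by sorted heading-date phenotype, and
  polycrossed into SYN1.
* **Year c+9** — SYN1 groups are intermated into SYN2 plots, phenotyped
  (and genotyped in genomic scenarios).
* **Year c+10** — the best 20 SYN2 plots are selected by the same index.
* **Year c+11** — SYN2 material becomes available as parent material and
  the terminal SYN3 generation is produced (it feeds no further selection).

The index is a weighted sum (weights 1/3) of trait values z-standardized
within the candidate cohort, which is what "equal emphasis" means
operationally; a raw-scale option is kept. All truncation selections break
ties by candidate id, so runs are replayable decision-for-decision.

Plot and greenhouse plants are distinct intermated offspring of the same F1
family: a plot cannot be dismantled into parents, which is why single plants
exist at all. Plot size, single-plant counts and group sizes are
configuration knobs with the defaults above.

## Scenarios and overlapping cycles

One cycle starts every year for 25 cycles in a 36-year horizon (cycle 25
completes in year 36 exactly). The five scenarios differ only in selection
machinery and parent recruitment:

| scenario | selection | independent cycles | later-cycle parents |
|----------|-----------|--------------------|---------------------|
| Phen-Y12 | phenotype | 11 | SYN2 group plants |
| Phen     | phenotype | 5  | F2 single plants + SYN2 group plants |
| GS-Y12   | GEBV      | 11 | SYN2 group plants |
| GS       | GEBV      | 5  | F2 single plants + SYN2 group plants |
| GS-SP    | GEBV      | 5  | F2 single plants + SYN2 single plants |

F2 single plants become available as parents in year c+5, SYN2 material in
year c+11; a cycle starting in year y may use anything available by year y,
pooled across all eligible cycles. Phenotypic scenarios draw parents
uniformly from the pool — there is no device for comparing plants across
cycles on phenotype — while genomic scenarios rank the pooled candidates by
GEBV index and keep the top 500 (reused round-robin if the pool is smaller,
as when only one cycle's 400 single plants exist). Pairs prefer parents from
different families; two distinct plants per pair is a hard constraint.
Parent count per cycle (500, giving 250 crosses) mirrors the cycle-1
structure, which is the only structure the program defines.

Phenotypic scenarios never touch genotypes for selection; genomic scenarios
never touch TBVs for selection — TBVs feed metrics only.

## Genomic prediction

Marker effects are estimated per trait with Bayesian ridge regression fitted
by a single-site Gibbs sampler with residual updating: a common Gaussian
prior on all 7000 SNP effects and scaled-inverse-\(\chi^2\) priors (5
degrees of freedom) on the marker-effect and residual variances. The prior
scales follow the conventional sample-variance rule with an even prior split
of var(y): the residual prior mode is \(0.5\,\mathrm{var}(y)\) and the
marker-variance prior mode is \(0.5\,\mathrm{var}(y) / \sum_j
\mathrm{var}(x_j)\); both the split and the degrees of freedom are
arguments. Dosage columns are centered by their training means and the same
centers are applied at prediction; the intercept is omitted from GEBVs,
which shifts nothing that a ranking can see.

The reference population holds one record per phenotyped plot (mean dosage
of 20 sampled plants, plot phenotype) and grows monotonically: each year
adds 250 F2 records (year c+3 of the launching cycle) and, once cycles
mature, 50 SYN2 records (year c+9). A selection event in year y trains on
records phenotyped by year y (F2 family selection: by year y − 1, since
its own cycle's records are the newest it can have seen over the preceding
winter). Fits are cached per training snapshot, and with fixed variance
components the sampler reproduces the closed-form ridge solution
\((X^\top X + \lambda I)^{-1} X^\top y\), \(\lambda = \sigma^2_e /
\sigma^2_a\), which is the main correctness oracle.

Chains default to 50,000 iterations with 10,000 burn-in (`"full"` profile);
the `"fast"` profile (5,000/1,000) is used for desk-scale work and testing,
where posterior means of this well-behaved conjugate model are already
stable.

## Metrics

* **Genetic gain**: per cycle and trait, the difference of mean F1 TBV from
  cycle 1, divided by the SD of cycle-1 F1 TBVs (an unselected stage).
* **Additive variance**: variance of the 250 F1 family mean TBVs, per
  cycle, standardized to cycle 1.
* **Accuracy**: Pearson correlations recorded per cycle and stage. For
  single plants (F2 SPs, SYN2 SPs) it is corr(GEBV, TBV) over the
  candidates. For SYN2 plots two readings exist and both are recorded:
  `SYN2_plot` correlates plot phenotype (or plot GEBV) with plot TBV over
  the 50 candidate plots; `SYN2_plant` pairs every member plant's TBV with
  its plot's phenotype. The plant-paired measure is the headline accuracy
  for phenotypic schemes because it answers the operational question —
  how well does a plot record rank the *plants* one must actually pick —
  and the within-group Mendelian variance it includes is exactly why
  random single-plant choice limits phenotypic programs (accuracies near
  0.15, flat over cycles). The plot-level reading is the natural one for
  GEBV-selected plots and is what improves as the reference grows.
* **LD and diversity**: within-variety \(r^2\) as squared Pearson
  correlation of genotype dosages (composite LD — plots are never phased in
  practice), with a within-variety MAF > 0.05 filter because LD is barely
  detectable when either locus is near fixation; binned decay up to 20 cM in
  1 cM bins, plus mean adjacent-SNP \(r^2\) and observed heterozygosity.

## Numerical and testing choices

Everything stochastic flows through R's RNG, including the C++ kernels
(gene dropping, mating, the Gibbs sampler), so a single `set.seed()` makes
full runs reproducible; replicate seeds are derived deterministically from
the base seed and stay below \(2^{31}\). Degenerate inputs fail loudly:
infeasible panels name the deficient chromosome, zero-variance phenotypes
return zero effects with a warning, and zero-variance calibration sets are
errors.

The test suite runs the founder simulation at full scale (2000 generations,
17,500-locus pool) because LD and heterozygosity targets are emergent and
scale-sensitive, but evaluates the breeding program at reduced scale where
only structure is under test: a 2-chromosome genome with 100 SNPs and 20
QTL per chromosome, 20 F1 families of 10, and a 300-iteration chain. The
accuracy targets that depend on full-sized references (250 plots, 7000
SNPs) are run at full scale with the fast chain and a handful of
replicates. The synthetic generator emulates drift-mutation-recombination
equilibrium and additive pleiotropic architecture; it does not model
genotype-by-environment interaction, dominance or epistasis, multi-location
trials, or genotyping error, so passing tests speak to the breeding logic
and estimation machinery, not to those features of real data.

## Known limitations

Tetraploid genetics, economic weighting of the index, optimum-contribution
selection and inbreeding management are out of scope. The within-cycle
calendar is a single authoritative table; real programs shift stages
opportunistically. Training snapshots serialize to CSV. The SYN3 stage is
produced but terminal, as in the program being modeled.
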