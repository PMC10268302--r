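---
title: "Methods: introgression statistics, load accounting, and clonal dynamics"
author: "clonintro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: introgression statistics, load accounting, and clonal dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`clonintro` implements the population-genomic toolkit needed to study gene
flow from a wild donor population into a clonally propagated crop: windowed
diversity and divergence statistics, the ABBA-BABA family of introgression
statistics, deleterious-load accounting stratified by region class, and a
forward Wright–Fisher simulator that contrasts outcrossing with clonal
propagation after a hybridization pulse.  Everything is validated on a
synthetic five-population system with known introgressed ancestry tracts.
This vignette documents the models, the conventions, and the design
decisions.

## Data model and coordinates

Genotypes live in a `genotype_matrix`: biallelic SNP sites × diploid
samples, with dosage counting copies of the coded allele (ALT on VCF input;
the derived allele after `polarize_by_outgroup()`).  Positions are 1-based
on input (VCF convention); all region and window arithmetic is 0-based
half-open (BED convention), and a site at position *p* occupies base
*p − 1*.  Polarization keeps a site only when every non-missing outgroup
genotype is homozygous for one allele; sites with polymorphic or entirely
missing outgroups are dropped rather than folded, because the D/fd/fdM
statistics and the unfolded site frequency spectrum require unambiguous
derived-allele polarity.

Windows are non-overlapping tiles; the trailing partial tile is kept and
flagged so genome-wide fractions remain well defined.  A window is *valid*
when it contains at least `min_snps` biallelic SNPs (100 by default, the
usual threshold for 50-kb windows on dense resequencing data; the
desk-scale synthetic analyses use 25 because the simulated site panel is
sparser).  Statistics in invalid windows are `NaN`, never 0, so that
quantile-based region selection skips them.

## Windowed statistics

Per site with derived frequency *p* estimated from the *n* non-missing
haplotypes of a group:

* π uses the unbiased estimator 2*p*(1−*p*)·*n*/(*n*−1); a window's π is
  the site sum divided by the full window length in bp, treating positions
  without a SNP record as invariant.  This reproduces per-bp magnitudes
  (around 10⁻³–10⁻⁴ here) from SNP-only input.
* D<sub>xy</sub> is the cross-group mismatch rate
  *p*<sub>A</sub>(1−*p*<sub>B</sub>) + *p*<sub>B</sub>(1−*p*<sub>A</sub>),
  summed and normalized the same way.  `dxy_difference()` implements the
  recipient-versus-control contrast (e.g. D<sub>xy</sub>(wine,donor) −
  D<sub>xy</sub>(table,donor)); negative values mean the first pair is the
  more similar one.
* F<sub>ST</sub> is Hudson's estimator as a ratio of sums over sites, which
  is robust to unequal sample sizes; a slightly negative estimate on
  low-divergence windows is reported as computed.
* PBS transforms pairwise F<sub>ST</sub> into branch lengths
  T = −log(1−F<sub>ST</sub>) and reports the focal branch length
  (T<sub>fb</sub> + T<sub>fc</sub> − T<sub>bc</sub>)/2.
* Per-sample heterozygosity divides the heterozygous call count by the
  number of retained SNP sites (a non-missing-denominator variant is
  available, since the choice matters for samples with uneven missingness).

Relatedness (`pairwise_pi_hat()`) follows the PLINK `--genome` method of
moments: observed identity-by-state counts are equated with their
expectations given cohort allele frequencies to solve for P(IBD = 0, 1, 2),
and PI_HAT = P(IBD=1)/2 + P(IBD=2).  Because frequencies come from a finite
cohort, each frequency monomial is replaced by its unbiased estimator under
sampling without replacement from the observed alleles (hypergeometric
factorial moments).  Negative intermediate probabilities are clamped to
zero and the triple renormalized.  The estimator is validated against
construction: a duplicated sample gives PI_HAT = 1, simulated unrelated
pairs ≈ 0, and a constructed parent–offspring pair ≈ 0.5.

## ABBA-BABA statistics

For an ordered trio (P1, P2, P3) with outgroup O and per-site derived
frequencies *p₁…p₄*: ABBA = (1−*p₁*)*p₂p₃*(1−*p₄*) and
BABA = *p₁*(1−*p₂*)*p₃*(1−*p₄*); D is the normalized window difference.
fd substitutes the higher of *p₂*, *p₃* (the inferred donor) for both in
the denominator, and is reported `NaN` for windows whose numerator sum is
not positive — fd is defined only for excess ABBA, and density plots need
honest missingness rather than zeros.  fdM switches to P1↔P3 sharing with a
negated sign at sites where *p₁* > *p₂*, making it symmetric about zero;
positive values mean donor sharing with P2.  Block-jackknife standard
errors over windows are provided for D, but region extraction uses
quantiles (`top_quantile_regions()`, ties at the threshold included), not
significance gates.

The f-branch summary assigns admixture-ratio signals to tree branches:
f(A,B,C) is the standard ratio Σ*p₃*(*p₂*−*p₁*) / Σ*p₃*(*p₃*−*p₁*) with the
donor standing in for itself in the denominator, and
fb(b,C) = median over A of [min over B ∈ descendants(b) of f(A,B,C)],
with A ranging over the sister clade of b, donors below b undefined, and
negatives floored at zero.

## Load accounting

Effect classes (dSNP/sSNP/SV) are consumed as input — variant-effect
prediction is out of scope — and the synthetic generator assigns classes
itself.  For each individual and region stratum the three load models are:
heterozygous load (count of heterozygous dSNPs), recessive load
(homozygous-derived dSNPs), and additive load (het + 2·hom); the
dSNP/sSNP ratio uses additive allele counts by default (a site-count
variant is a flag).  Densities divide by stratum length, and random
length-matched control regions (uniform placement, non-overlapping within a
replicate, seed-reproducible) provide the negative control distribution.

The introgressed-allele spectrum uses an operational candidate definition,
since none is standard: a derived allele inside a called introgressed
region with frequency ≥ 0.2 in the donor and ≤ 0 in every reference group
(both thresholds configurable).  Both the allele-frequency and the
carrier-fraction binnings are emitted, together with the heterozygous share
of carriers.

SFS comparisons between effect classes use a paired signed-rank statistic
over matched frequency bins; identical spectra give statistic 0 and p = 1
by construction (the underlying `wilcox.test` cannot handle the all-tie
case).

## The forward simulator

A diploid Wright–Fisher engine with two reproduction modes.  Fitness is
multiplicative: w = Π (1+s)^hom (1+hs)^het with h = 0.5 by default
(deleterious dominance can be overridden, e.g. h = 0 for full
recessivity).  Outcrossing samples two distinct parents proportional to
fitness and forms recombinant gametes (crossover count Poisson(rL),
breakpoints uniform); clonal propagation samples one parent and copies the
diploid genotype exactly.  Mutation is infinite-alleles per site at rate
μL per gamete (per haplotype for clones — both haplotypes of a clone
mutate, which is the mechanism by which clonal lineages accumulate
heterozygosity without bound), so per-site heterozygosity has the
closed-form neutral equilibrium θ/(1+θ) with θ = 4Nμ′, which the test
suite verifies to 15%.

A hybridization pulse replaces a fraction of recipients with F1s (one
recombinant donor gamete, one recipient gamete).  Every position inherited
from the donor gamete carries an introgressed-origin flag; flags propagate
only through reproduction, and a new mutation clears the flag of the copy
it overwrites.  Introgressed *copies* are flagged derived alleles; truth
*tracts* are maximal runs of flagged positions.

### The canonical pulse experiment

`pulse_experiment_config()` fixes the desk-scale study conditions used by
the analysis scripts and the acceptance checks: N = 200 recipients, 150
donor-fixed differential sites (half beneficial, exponential effects with
mean s = 0.03; half deleterious, gamma shape 2 with mean −0.03; h = 0.5), a
pulse replacing 15% of recipients, 10 outcrossing generations, then strict
clonality; the comparison arm outcrosses throughout.  These values were
fixed by four constraints, decided at design time:

* the per-F1 hybrid load (≈ K_del·h·|s̄|) must stay near 1, or selection
  removes the donor material wholesale before backcrossing can rescue it;
* per-allele selection must be weak enough (N|s| ≈ 5–10) that the
  outcrossing arm approaches its equilibrium slowly, while the clone-level
  fitness variance (which aggregates across a clone's ~tens of donor
  alleles) is large enough that clonal takeover is decisive within a few
  hundred generations — this separation is what produces the clonal-faster
  contrast;
* the deleterious DFE uses gamma shape 2 rather than a heavy-tailed shape,
  so that few deleterious draws are effectively neutral; otherwise the
  deleterious-versus-beneficial comparison of surviving sites reflects
  per-replicate DFE sampling noise rather than selection;
* new mutation is negligible (μ = 10⁻⁹/bp) during the experiment: a
  continuing influx of beneficial mutations causes clonal interference and
  indefinitely delays the clonal plateau.

"Equilibrium" is operationalized by a plateau rule: the first generation
from which the 50-generation sliding mean of total introgressed copies
changes by less than 1% — and keeps doing so for the remainder of the run.
The sustained-change requirement matters: the literal first crossing fires
at the transient trough where early purging of deleterious copies balances
the rise of beneficial ones.  A trajectory absorbed at zero counts as
plateaued; a trajectory still changing at the end of the run has no plateau
(which, in the outcrossing arm, itself demonstrates the slower dynamics).

Two desk-scale operationalizations of aggregate claims: the
rise-then-plateau property of total introgressed copies is asserted on the
across-replicate mean trajectory (the population-scale claim is about the
expected trajectory), and the deleterious ≤ beneficial comparison of
segregating introgressed sites is made on time-averaged counts of the
outcrossing arm — at these population sizes the end-of-run segregating
counts are small, nearly absorbed numbers whose instantaneous comparison is
dominated by noise, while the time average carries the purge-phase
asymmetry that is the substance of the claim.  The clonal arm's equilibrium
is characterized instead by its frequency spectrum: after takeover the
population is a single clone heterozygous at its surviving donor sites, so
every surviving introgressed allele sits at exactly 50% — the modal-bin
check the acceptance script recomputes.

## The synthetic scenario

`scenario_config()` encodes the study system at desk scale: an ancestral
population splits into a low-N EU-like donor (N = 30) and an ME-like
lineage (N = 80) that successively yields ME1, ME2 and a cultivated
ancestor, which splits into table and wine analogs; after a short
independent history both cultivated analogs receive a donor pulse — 15%
into the wine analog and 3% into the table analog, preserving the
five-fold asymmetry — followed by backcrossing and a recent clonal phase.
Branch lengths are scaled so that drift divergence is moderate
(t/2N ≈ 0.2 between cultivated analogs and their wild source, ≈ 1.4 on the
donor branch, giving the donor clearly reduced diversity); absolute times
are out of scope, topology and rate ratios are preserved.  Ancestral
standing variation is drawn from the neutral SFS (P(count = i) ∝ 1/i) at
linkage equilibrium, and subsequent drift, recombination and admixture
create the linkage structure; this is the main idealization relative to
real data, along with a uniform recombination rate, a single contig, the
biallelic collapse of recurrent mutations, and effect classes assigned
independently of position.  Passing tests therefore demonstrate the
correctness and sensitivity of the estimators under a known demography —
not robustness to background selection, variable recombination, or
reference bias.

Truth tracts are defined from origin flags over the *emitted* (polymorphic)
sites — a run of flagged sites extends midpoint-to-midpoint toward the
flanking native sites, since tract boundaries between markers are
unobservable — so every truth tract overlaps at least one VCF record by
construction.  The fd-versus-truth contrast is coverage-weighted: each
window's fd is weighted by the fraction of window × recipient-haplotype
space covered by tracts (and by the complement for the background mean),
because after a recent pulse the union of per-sample tracts can touch
nearly every window, which would leave a binary tract/non-tract window
classification undefined.

`spike_load()` plants a recoverable ground truth: dSNP labels are assigned
so the heterozygous-dSNP density of the recipient group inside the tract
union is a chosen multiple of the outside density (the in/out split of the
dSNP budget is solved from the observed heterozygote counts, then assigned
randomly, keeping the draw whose realized enrichment is closest to the
target; the realized value is recorded).  The acceptance suite recovers a
3.0-fold spike as 3.0 ± 0.5 over 20 seeds using only the emitted files.

## Problem sizes and reproducibility

All analyses are seed-deterministic: one root seed per run, per-replicate
streams derived from it, and byte-identical outputs under identical
configuration.  The analysis scripts and tests use a 1-Mb genome with
~3,000 site slots and five populations of 30–80 diploids (scenario), and
the pulse experiment above with 20 replicates and horizons of 1,000–2,000
generations — sizes chosen so the whole pipeline, including property
suites, runs on a laptop in minutes.  Known limitations: no phasing or
genotype likelihoods, no multiallelic decomposition, no selfing, no
spatial structure, and the simulator tracks a fixed panel of site slots
rather than a continuous sequence.
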