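---
title: "Models and methods in hybridorigin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in hybridorigin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hybridorigin)
```

# Overview

`hybridorigin` implements a complete inference chain for the question "is
this taxon a hybrid, and of whom?" from multilocus sequence data: per-locus
polymorphism and neutrality statistics, genetic-distance ordination, Bayesian
admixture clustering with Evanno's $\Delta K$, six-class hybrid-genotype
assignment, chloroplast genetic typing with cytonuclear-discordance
reporting, and coalescent-based approximate Bayesian computation (ABC) over
explicit demographic scenarios with pulse admixture. A synthetic-data
generator produces fully labelled study-analogue datasets so that every
stage can be validated against known truth.

This vignette records the models, their assumptions, the tunable parameters,
and the numerical and design choices, in that order of importance to a user.

# Data model

A locus is an aligned character matrix over `{A,C,G,T,-,N}`. Nuclear loci
carry two phased haplotype rows per diploid individual (`ind/1`, `ind/2`);
chloroplast loci carry one row per individual (maternal, effectively
haploid). Inputs are assumed phased and aligned; phasing and alignment are
out of scope. Internally coordinates are 0-based half-open; all user-facing
reports are 1-based.

Columns containing `-` or `N` in any row are excluded before polymorphism
statistics (complete deletion). The deletion policy of the original
diversity software is not documented for this data type; complete deletion
is the common default and is applied uniformly.

# Diversity and neutrality statistics

For a sample of $n$ haplotypes of analysed length $L$:
$\pi = \sum_{i<j} d_{ij} / \binom{n}{2} L$,
$\theta_W = S / (a_1 L)$ with $a_1 = \sum_{i=1}^{n-1} 1/i$, plus the
segregating-site count $S$, distinct-haplotype count $N_h$, and the mean
pairwise difference $k$ (a count, not per site).

Tajima's $D$ uses the standard 1989 constants. Fu and Li's $D^*$ and $F^*$
are the within-species (no-outgroup) versions built from the total mutation
count $\eta$ (states minus one, summed over columns) and the singleton count
$\eta_s$, with the corrected variance constants. All three are reported as
explicitly undefined (`NA` plus a `tests_defined` flag) when $S = 0$, never
as silent zeros. The implementation is validated two ways: exact agreement
with brute-force pairwise enumeration on a small alignment, and a
Monte-Carlo null — across 2000 neutral coalescent replicates ($n = 20$,
$\theta = 5$ per locus) the mean of $D$ stays within $\pm 0.1$ of zero and
the means of $D^*$ and $F^*$ within $\pm 0.15$.

## Maximum-likelihood HKA test

The polymorphism/divergence contrast is modelled per locus $i$ as
independent Poisson counts,
$S_i \sim \mathrm{Pois}(k_i \theta_i L_i a_{n_i})$ and
$\mathrm{Div}_i \sim \mathrm{Pois}(\theta_i L_i (T + 1))$, with $\theta_i$
the per-site scaled mutation rate, $T$ the divergence time in $2N$ units,
and $k_i$ a selection multiplier fixed to 1 under neutrality and freed on a
declared candidate set under the selection model. The likelihood-ratio
statistic is referred to a $\chi^2$ with one degree of freedom per candidate
locus.

Numerically, both models are fitted by *profile likelihood*: for fixed $T$
the maximising $\theta_i$ (and $k_i$) have closed forms, so the whole fit is
a one-dimensional optimisation over $\log T$ on $[10^{-4}, 10^6]$. This is
exact for this likelihood, deterministic, and removes any dependence on
restart heuristics; a multi-start quasi-Newton search over the full
parameter vector reaches the same optimum but slower and stochastically.
Calibration on data simulated from the null gives a type-I error within
$5\% \pm 3\%$ at the nominal 5% level, and one locus with fivefold
polymorphism excess is detected in $\ge 80\%$ of replicates.

Divergence counts are raw differences between the ingroup consensus and a
single outgroup sequence on fully resolved columns, without multiple-hit
correction — appropriate for closely related taxa; the outgroup is an
explicit argument.

# Genetic distance and ordination

The between-individual distance at one locus is the number of allele copies
not shared under the better of the two possible copy pairings (0, 1 or 2),
summed over loci scored in both individuals; alleles are haplotype classes
from `collapse_haplotypes()`. Ordination is classical metric scaling (Gower
double-centering of $-\tfrac12 D^2$, eigendecomposition, coordinates scaled
by the square roots of the positive eigenvalues); it reproduces
`stats::cmdscale` and reported variance fractions use positive eigenvalue
mass only.

# Admixture clustering

`admixture_gibbs()` is a Gibbs sampler for the classic admixture model:
every allele copy has a latent cluster of origin; individual admixture
proportions $Q_i$ get a symmetric Dirichlet($\alpha$) prior with $\alpha$
given a uniform$(0, 10)$ hyperprior updated by a Metropolis step (normal
proposal, sd 0.25); cluster allele frequencies get Dirichlet(1) priors. The
model log-evidence is estimated as
$\widehat{\ln P(D)} = \overline{\ln L} - \mathrm{var}(\ln L)/2$ over
post-burn-in sweeps. Defaults (`iters = 600`, `burnin = 200`) are desk-scale
test settings; study-scale runs should use the conventional
100,000/200,000-sweep protocol with 10 replicates per $K$, which the
`admixture_replicates()` seeding scheme (replicate $r$ of a given $K$ uses
`seed + r + 1000 K`) supports directly.

The independent-frequency model is the baseline. The correlated-frequency
(F-model) variant — cluster frequencies shrunk toward a latent ancestral
vector with per-cluster drift parameters under uniform(0,1) priors, all
updated by Metropolis — is available via `correlated = TRUE`. For the
strongly diverged fixtures used in validation the two variants agree; the
baseline is simpler to audit.

## Choosing K

`evanno_delta_k()` computes
$\Delta K = |\bar L(K{+}1) - 2\bar L(K) + \bar L(K{-}1)| / \mathrm{sd}(L(K))$
from replicate log-evidence values; it is undefined at the endpoints and
where the replicate standard deviation vanishes.

One methodological point deserves emphasis: under a *perfectly symmetric*
multi-population truth, every replicate run at $K$ below the true value
finds the same merge, the replicate spread collapses, and $\Delta K$
degenerates toward its well-known bias for the uppermost hierarchical level
($K = 2$). The package's three-population validation fixture therefore uses
unequal effective sizes (2000/5000/10000) and unequal sample counts
(16/24/32) — the situation of any real multi-taxon sample — under which
$\Delta K$ recovers the true $K = 3$ in a clear majority of replicate sets.
Symmetric fixtures are a worst case for this statistic, not a neutral one.

# Six-class hybrid assignment

Candidates plus two parental reference panels are classified into
{Pure1, Pure2, F1, F2, BC1, BC2} using the Mendelian gene-copy-origin
frequencies $(p_{11}, p_{12}, p_{22})$ of each class. The genotype
likelihood mixes Hardy-Weinberg terms within each parental gene pool with
the between-pool term. The Gibbs sampler alternates: gene-copy origins given
classes and frequencies; classes given marginal genotype likelihoods; class
mixing proportions (Dirichlet(1) over six classes); and parental allele
frequencies under either a Jeffreys-like Dirichlet($1/A$) or a uniform
Dirichlet(1) prior per locus ($A$ = allele count). `classify_hybrids()` runs
both priors and warns when their posteriors disagree by more than 0.1
anywhere (a convergence diagnostic). The `z` option fixes declared reference
individuals to their pure class while letting them inform frequency
estimation; the `s` option excludes individuals from frequency estimation
entirely. Only two parental species are modelled — second-generation
backcrosses and three-way hybrids are outside this classifier (trihybrids
are handled by the ABC scenario layer).

With ten strongly diagnostic loci, BC and Pure classes overlap in genotype
space (a backcross can be homozygous parental at every locus with
probability $2^{-10}$ per gamete); posterior mass, not a hard threshold, is
reported, and modal-class summaries should be read with that overlap in
mind.

# Coalescent engine

Scenarios are demographic DAGs read backward in time: populations with
constant sizes $N$, `split(t, a -> b)` events moving all lineages of `a`
into `b`, and `admix(t, a; b, c, r)` pulses sending each lineage of `a` to
`b` with probability `r`, else `c`. Within a population, pairs coalesce at
rate $k(k-1)/2$ per $2N$ generations; waiting times are exponential and
events interrupt them exactly. Scenario validation rejects negative
times/rates and any event structure that strands lineages away from a single
root — before a run starts, not during it.

Mutations are Jukes-Cantor, Poisson-placed on branches at rate
$\mu \cdot \mathrm{length}$ per generation. Loci are unlinked and free of
intralocus recombination (the upstream workflow trims recombining fragments;
a recombination model is deliberately out of scope). Diploids are formed by
pairing consecutive sampled lineages. In the synthetic generator the six
chloroplast loci are simulated as one completely linked block — one
genealogy, as for a non-recombining maternal molecule — and then cut into
per-locus alignments.

The engine is C++ (via Rcpp) because the ABC layer needs millions of locus
simulations; all randomness flows through R's RNG, so a single `set.seed()`
reproduces every simulation bit for bit. The fast path used by ABC
propagates mutations only at variable sites; the closed-form checks
($E[\pi] = \theta$, $E[S] = a_n \theta L$, $E[T_{MRCA}] = 2N$ for $n = 2$,
all within 5% at 5000 replicates) and a distributional equivalence test
(admixture with $r = 1$ vs a plain split; split at $t \to 0$ vs panmixia)
guard both paths.

# ABC scenario comparison

Two scenario libraries mirror the two study designs. The *trio* library
(two candidate parents, one putative hybrid) holds seven scenarios: a
simultaneous three-way split; three two-split topologies; and three
hybrid-origin scenarios, one per choice of hybrid population. The *quartet*
library (three parents, one putative trihybrid) holds: origin from the root
ancestor; descent from the third species; descent from the first pair's
ancestor; a hybrid of the third species and that ancestor; and three
two-step trihybrid orders via an intermediate lineage. The upstream
description of the two-step scenarios lists two of them with identical
wording; the library implements the three *distinct* cross orders and
documents the mapping, which is the only self-consistent reading.

Priors default to log-uniform $N \in [10^2, 10^5]$, uniform
$t \in [10, 10^5]$ generations under each scenario's ordering constraints
(enforced by resampling), and uniform $r \in [0.05, 0.95]$; all are
user-overridable, since the appropriate ranges are study-specific.

Summary statistics per population: $N_h$, $S$, mean and variance of
pairwise difference counts, Tajima's $D$; per population pair: mean
between-population differences and Hudson's $F_{ST} = 1 - H_w/H_b$.
Statistics are averaged over loci. Undefined entries ($D$ at $S=0$;
$F_{ST}$ with $H_b = 0$) are imputed as 0 and masked. This is the standard
sequence-statistic set of DIYABC-style analyses; the R (observed-data) and
C++ (simulation) paths compute identical definitions, which the
scenario-recovery tests exercise end to end.

Rejection retains the closest `ceiling(tolerance * n)` simulations by
Euclidean distance on statistics standardised by the reference table's
standard deviations (zero-variance statistics are dropped with a warning).
Posterior scenario probabilities come from multinomial logistic regression
of the scenario label on statistics centred at the observed vector,
evaluated at the origin, with nonparametric-bootstrap 95% intervals (200
resamples by default; the regression falls back to retained proportions if
it cannot be fitted). Parameter estimation under the winning scenario is
out of scope.

Because the reference table does not depend on the observed data, recovery
experiments reuse one 10,000-draws-per-scenario table across all
pseudo-observed replicates. At the validation conditions (10 loci of 500 bp,
10 haplotypes per population, $N = 5000$, recent admixture at $r = 0.5$, 1%
tolerance) the generating trio scenario wins in 20/20 replicates and the
generating quartet two-step scenario in 19-20/20, with the occasional miss
going to the competing two-step order — the expected confusion mode.

# Chloroplast typing and cytonuclear discordance

Candidates are typed by the reference set containing their
minimum-Hamming-distance chloroplast haplotype on the concatenated
chloroplast alignment (complete deletion); ties across sets yield an
explicit ambiguity flag instead of a label. This distance rule substitutes
for reading clade membership off a phylogeny and reproduces it whenever the
reference groups are well separated — the regime in which tree-based typing
is itself reliable. Reference sets must contain only verified pure
individuals; including introgressed members of a taxon would contaminate
the set with the other side's haplotypes.

Count tables cross-tabulate types by locality with row totals, an overall
total, and each type's share rounded half-up to one decimal. When an
externally stated total disagrees with the column sums, the computed total
is reported and the discrepancy flagged — stated totals in secondary
sources are occasionally internally inconsistent, and silently adopting
them would propagate the error.

The discordance report compares each individual's modal nuclear cluster
with its chloroplast type. A cluster's expected type is the majority type
among individuals confidently assigned to it (modal $Q \ge$ threshold,
default 0.9). Flagged patterns: *hybrid* (admixed nuclear genome — its
chloroplast necessarily matches only the maternal side) and *introgression*
(confident nuclear assignment, other side's chloroplast). The threshold
trades sensitivity for false flags; 0.9 is appropriate for strongly
diverged parents and should be lowered with caution.

# The synthetic generator

`study_fixture()` builds a labelled analogue of a three-species
hybrid-zone study: species A and C sisters (split 40,000 generations ago),
B diverging at 80,000, $N = 5000$, 10 nuclear loci of 400-800 bp at target
per-site diversity 0.005, six chloroplast loci of 900-2500 bp at 0.0005
(an order of magnitude lower, as organellar data typically are), 20 diploid
individuals per species; a hybrid swarm of 18 F1(A×B) with 2 F2s (maternal
B); a second swarm of 24 F1(C×A) (maternal C) with 2 trihybrids
((C×A)×B, maternal B) — 2/26 = 7.7% of that taxon; and 4 introgressed
individuals inside species C (backcross construction with B, maternal B).
The divergence times sit at $8N$-$16N$ generations, deep enough that the
species form fixed clusters, matching a study system of distinct species
rather than an incipient radiation.

Hybrids are constructed *mechanically* from simulated parental haplotypes
(random parental haplotype per locus for F1s; random gametes for F2, BC and
trihybrid constructions; chloroplast copied from a random maternal-species
individual) rather than simulated demographically. This gives exact truth
labels for scoring classifiers. The ABC layer's pseudo-observed datasets
are, by contrast, simulated demographically under explicit scenarios — both
paths exist deliberately and test different things.

What the generator does *not* emulate: sequencing and phasing error,
recombination within loci, gene flow after hybrid formation, selection,
population structure within species, and missing data. Passing tests
therefore demonstrate correctness of the inference machinery under the
stated models, not robustness of the science to violations of them; on real
data, phasing quality and recombination trimming remain the user's
responsibility.

# Problem sizes and runtime choices

The test and acceptance workloads use: 2000 neutral replicates for the
$D$/$D^*$/$F^*$ calibration; 200 replicates for the ML-HKA error rates;
5000 replicates for the coalescent closed forms; 600-sweep admixture chains
(400 for the $\Delta K$ sets, 10 sets of 3 replicates over $K = 1..5$);
1500-sweep classifier chains; and ABC reference tables of 10,000 draws per
scenario with 20 pseudo-observed replicates per library. These sizes give
Monte-Carlo error comfortably inside each check's tolerance; production
analyses should scale chain lengths up by two orders of magnitude (the
conventional protocols cited above) and ABC tables to $10^6$ draws per
scenario.

# Known limitations

- The admixture sampler does not implement the location-prior or linkage
  models; hierarchical reruns on taxon subsets replace migrant-detection
  priors.
- The classifier is limited to two parental species and the six default
  classes; later-generation hybrids beyond F2/BC are not modelled.
- ABC confidence intervals are bootstrap envelopes over the retained set;
  they quantify regression uncertainty at the chosen tolerance, not
  tolerance sensitivity.
- Chloroplast typing assumes the reference groups are separable; with
  shared or introgressed chloroplast haplotypes the ambiguity flag, not the
  label, is the informative output.
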