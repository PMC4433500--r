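---
title: "Pedigree-based carrier tracing and linked-marker phase inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-based carrier tracing and linked-marker phase inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedilink)
```

## The problem

Boxer arrhythmogenic right ventricular cardiomyopathy (ARVC) is a late-onset
heart-muscle disease segregating as an autosomal dominant with very low
penetrance: carriers of the disease allele rarely develop clinical disease
within a breeding lifetime, so the allele "skips" generations and ordinary
segregation analysis has nothing to see. A deletion in the Striatin (STRN)
gene on dog chromosome 17 was proposed as the causal mutation, but dogs with
and without the deletion occur among both cases and normals. `pedilink`
implements the rule-based genetic appraisal that resolves this picture:

1. **Obligate-transmitter identification.** A dog demonstrably carries the
   allele when it is affected, or when it has produced affected offspring in
   litters with *several different mates* (default threshold: two). One
   affected litter from one mate never suffices — the allele could have come
   from the other side.
2. **Line-of-descent tracing.** Transmitters are traced upward through other
   transmitters to maximal ancestors ("sources"); sources joined by a shared
   descendant transmitter form one line. Dogs flagged as imports stop the
   walk — foreign ancestry is out of evidence.
3. **Clear-by-pedigree classification.** A dog with no source among its
   ancestors (or itself) is classified free of the allele *by exclusion*.
4. **Phase inference and recombination detection.** Treating the STRN
   deletion as a linked biallelic marker, each carrier's disease allele lies
   either on a deletion-bearing chromosome (*coupling*) or on a wild-type
   chromosome (*repulsion*). Phase switches along a transmission chain are
   meiotic recombination events — the evidence that the marker is linked to,
   but distinct from, the disease locus.
5. **Association statistics.** Pearson chi-square between group genotype
   tables, a Hardy-Weinberg chi-square within a group, and a pooled-variance
   t test for onset ages.
6. **Penetrance estimation** from the segregation deficit in carrier x clear
   matings.

A gene-dropping simulator generates pedigrees with known ground truth so
every rule can be tested for soundness and calibration.

## The phase rules and why they are what they are

A carrier that is marker-homozygous has no choice about which chromosome
carries the disease allele: `HOM` forces coupling, `WT` (wild-type
homozygote) forces repulsion, both with certainty grade
`certain_by_homozygosity`. Marker heterozygotes are intrinsically ambiguous.

One propagation step is nevertheless *forced*. Consider a carrier child,
marker-heterozygous, whose only carrier parent is marker-homozygous with
certain phase. Enumerate that parent's gametes: both of its chromosomes
carry the same marker allele, so whether or not a crossover occurs the
transmitted marker allele is fixed, and the disease allele (which the child
received from this parent, its other parent being no carrier) arrives on a
chromosome of known marker type. The child's phase equals the parent's, with
no recombination assumption anywhere. We label such calls `propagated` and
treat them as reliable anchors; propagation is *not* chained through
marker-heterozygous parents, whose gametes genuinely depend on crossovers.

Both parents being carriers blocks propagation (and recombination-event
attribution): the disease allele's parental origin is then unknowable from
rules alone.

### Grading recombination events

A crossover is observable only in the gamete of a parent heterozygous at
both loci, and only when the receiving child reveals its phase through
marker homozygosity. `detect_recombination()` therefore grades a
parent-child phase mismatch `certain` when

* the parent is marker-HET with a forced (`propagated`) phase, the child is
  certain-by-homozygosity, and the child has exactly one carrier parent; or
* both endpoints are certain-by-homozygosity — a configuration that
  Mendelian-consistent genotypes cannot produce in one meiosis, so it flags
  recombination upstream or a data error, and is honoured as recorded.

Everything else with two known but unequal phases is `possible`, including
mismatches across multi-meiosis chains through untyped carriers (reported
against the whole path). A `certain` event in simulated data always
coincides with a true crossover in that meiosis when no hidden carriers
exist (penetrance 1); at lower penetrance an undetected carrier co-parent
can in principle mislead the attribution, which is exactly why the field
data's events remain "possible sites" rather than counts.

### Detection-rate calibration

Among *informative meioses* — marker-HET carrier parent with known phase,
carrier child certain-by-homozygosity, exactly one carrier parent — the
fraction showing a certain event estimates the recombination fraction
$\theta$, but only when the co-parent transmits each marker allele with
probability $\tfrac12$. For a coupling-phase parent the child reveals itself
as wild-type homozygote with probability $\theta(1-q)$ (event) and as
deletion homozygote with probability $(1-\theta)q$ (no event), where $q$ is
the co-parent's probability of transmitting the deletion allele, giving

$$\Pr(\text{event}\mid\text{informative}) =
\frac{\theta(1-q)}{\theta(1-q) + (1-\theta)q},$$

which equals $\theta$ iff $q = \tfrac12$; repulsion-phase parents give the
mirror-image expression. The calibration world in the acceptance suite is
therefore stated, before any test was run, as: founder marker-mutation
frequency $0.5$, penetrance 1, full typing, imports entering in *both*
phases (`import_phase = "per_import"`) so that forced marker alleles from
coupling and repulsion sources balance, and kin-avoidant mate assignment
(`avoid_kin_matings = TRUE`). The last matters because in a popular-sire
pedigree a carrier's mate is often a half-sib from the same import lineage
and therefore enriched in that lineage's forced marker allele, pulling $q$
off one half and the measured rate below $\theta$. These are properties of
those worlds, not defects of the detector: the suite separately checks that
every certain event coincides with a true crossover in the simulator's
meiosis log.

## Penetrance estimation and ascertainment

Under the dominant model half the offspring of a carrier x clear mating are
carriers, so the affected fraction estimates (penetrance)/2 and
`segregation_summary()` reports twice the observed fraction with a Wilson
95% interval (well-behaved at litter-sized counts). Carrier x carrier
matings are excluded: their expected carrier fraction is not one half and
the fate of disease-homozygotes is unknown.

Carriers identified *through their affected progeny* are ascertained through
the very offspring being counted, which biases the fraction upward at low
penetrance (the proband problem). `carrier_basis = "obligate"` restricts the
summary to affected parents, whose carrier status is independent of their
offspring, and is the setting used for parameter-recovery checks; the
default `"any"` mirrors the field practice of pooling all deduced carriers
and is the right descriptive summary for real data, read with that caveat.
Age censoring is handled only in the simulator — a carrier whose onset falls
beyond the follow-up horizon is recorded unaffected — because field records
cannot distinguish "not yet affected" from "never affected".

## What the simulator emulates, and what it does not

`simulate_pedigree()` drops a two-locus haplotype (marker allele, disease
allele; one recombination interval, crossover probability $\theta$ per
gamete) down a generated pedigree:

* **Population structure.** Discrete generations; every female mated once
  per generation under a popular-sire scheme (each sire serves
  `mates_per_sire` dams, default 3), with carrier males given stud priority
  — mirroring how a handful of much-used show sires historically spread the
  allele. Litter sizes are Poisson(6.5) truncated at one, the published
  mean Boxer litter size.
* **Disease model.** The allele enters only through `n_import_carriers`
  founder males ("imports"); no phenocopies, no de-novo mutation, no
  disease-homozygotes modelled. Penetrance default 0.25 (the paper reports
  only "far lower" than a literature figure of ~80%; 0.25 makes skipped
  generations the norm, as described). Onset age is log-normal with median
  7 years (published median) and log-sd 0.55, spanning roughly 2.3-21 years
  for the central 95% — consistent with the printed "<1 to over 10 years"
  range; follow-up censoring defaults to 10 years.
* **Marker.** Founders draw marker genotypes at Hardy-Weinberg proportions
  with mutation frequency 0.42 by default (loosely matched to the normal
  rows of the published genotype table; configurable, never asserted as a
  population estimate). Typing completeness defaults to 0.7.
* **Sexes** are 50/50, independent of genotype.

Two switches deserve comment because the soundness guarantees depend on
them. With `avoid_carrier_matings = TRUE` carrier dams are spread one per
sire (non-carrier sires first, overflow to carrier sires): a non-carrier
stud then never accumulates two carrier mates, so the several-mates rule
cannot fire on a non-carrier — the regime the multi-mate deduction is valid
in, and the reason carrier x carrier matings are rare, as in the field
data. With `imports_affected = TRUE` the imports are recorded affected
regardless of penetrance, modelling founders known to come from the original
disease stock; every source is then identifiable and no true carrier can end
up clear-by-pedigree. With unidentifiable sources (an import that happens to
leave no affected descendants) hidden carriers *will* be classified clear —
that is a property of classification by exclusion, not a bug, and it is why
the breed section "defined by exclusion" is claimed free *or at very low
frequency*.

A green simulation test therefore establishes that the rules are sound and
calibrated in the stated world; it cannot establish that real Kennel Club
pedigrees satisfy that world's assumptions (complete parentage records,
single-origin allele, no phenocopies).

## Statistical choices

* **No Yates continuity correction** anywhere: the uncorrected Pearson
  statistic reproduces all three published p-values (0.002, 0.081, 0.057)
  from the printed margins; a corrected statistic does not.
* Genotype columns with zero margin are dropped before computing degrees of
  freedom (needed when a group lacks a genotype class entirely).
* The Hardy-Weinberg test uses the chi-square approximation with one degree
  of freedom, not an exact test — again because that is what the printed
  value corresponds to at these counts. Monomorphic samples return
  statistic 0, p = 1, with a warning note.
* The onset-age test is Student's pooled-variance t (not Welch), matching
  the published description; it is provided as a generic operation — the
  raw ages behind the published comparison are not printed, so it has no
  reproducible target.
* One published footnote value (P = 0.0597 for all cases vs all normals) is
  not reproducible from any natural pooling of the printed rows; pooling
  the three case rows against the two normal rows gives chi-square = 1.03,
  p = 0.597, strongly suggesting a misplaced decimal point. The test is not
  tuned to force it.

## Numerical and design notes

* Kinship uses the classical recursion on the later-born individual with
  memoisation; inbreeding F(x) is the kinship of x's parents, 0 with any
  missing parent (the missing side is an anonymous unrelated founder). The
  suite checks it against an independent path-counting oracle.
* Cycle detection is wave elimination on child-to-parent edges; the error
  names a witness cycle.
* "Several different mates" is a configurable threshold, `min_mates = 2` by
  default — the weakest reading that still excludes one-litter coincidence.
* Ties between candidate sources that are ancestors of one another resolve
  to the more ancestral dog (maximality); line labels are assigned in
  pedigree order, so they are deterministic for a given file.
* Bridge (inferred-carrier) calls require a *forced conduit*: walking up
  from a carrier-evidence dog, a parent is called only when it is the sole
  at-risk side. A dog merely sandwiched between evidence is not called —
  the allele can flow through a co-parent — which is also why inbreeding
  within a line (both sides at risk) blocks the call.
* Ages are in years; a printed "<1" is encoded 0.5. Litters group by
  (sire, dam, litter key), one litter per pair when no key is recorded.
* Untyped dogs never block genotype tables; they are dropped with a count.
  External-study dogs carried in the `group` column are excluded from the
  per-line and normal rosters and reported as their own rows.

## Known limitations

* No likelihood-based segregation or LOD-score linkage analysis — the
  artifact reproduces a rule-based argument, and theta is estimated only on
  simulator truth counts.
* Recombination events in real (partially typed, low-penetrance) data are
  mostly `possible`, not `certain`; the package reports them against paths
  rather than inventing per-meiosis locations.
* The penetrance estimator ignores age structure beyond the simulator's
  censoring switch; no Kaplan-Meier-style penetrance curve is attempted
  because no onset distribution is published beyond the median.
* Cohort-level published counts (n = 194; lines of 82/76/25 dogs) depend on
  private pedigree records and are used only to scale simulations.
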