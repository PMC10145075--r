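---
title: "SNP-based screening of essentially derived varieties: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP-based screening of essentially derived varieties: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpEDV)
```

## Scope and model

`snpEDV` operationalizes essentially-derived-variety (EDV) screening for a
clonally propagated crop from biallelic diploid SNP genotypes. Everything
runs on genotype *classes* — homozygous reference (0), heterozygous (1),
homozygous alternate (2), missing (NA) — because the similarity statistic
at the center of the method is defined on classes, not alleles. Phase is
discarded on VCF import and half-calls (`./1`) are conservatively treated
as missing.

The pipeline stages and their statistical content:

**Per-locus diversity.** For each locus, over called genotypes only:
missing rate, alternate-allele frequency, MAF, observed heterozygosity
(fraction heterozygous), gene diversity $GD = 1 - \sum_i f_i^2$ and
Botstein's polymorphic information content
$PIC = 1 - \sum_i f_i^2 - \sum_{i<j} 2 f_i^2 f_j^2$. Both GD and PIC are
exposed under two conventions: plugging in the two allele frequencies
(bounds: GD ≤ 0.5, PIC ≤ 0.375 for a biallelic SNP) or the three
genotype-class frequencies (GD ≤ 2/3, PIC ≤ 16/27 ≈ 0.593). The second
convention exists because published per-SNP panel tables in this domain
report GD and PIC values above the allele-based biallelic maxima, which is
only attainable when genotype classes are treated as the states. The
allele convention is the default everywhere; a locus with zero called
genotypes propagates flagged `NA` statistics, never silent zeros.

**Two-stage SNP filtering.** Candidates require MAF strictly above 0.1,
missing rate strictly below 0.20, and no other variant within 150 bp on
the same chromosome (both members of a close pair are dropped). The
flanking rule is operationalized on the call set itself — true flanking
sequence invariance would require the raw reads, which are out of scope;
within a call set, a neighboring variant is exactly what would compromise
primer or probe design around the site. The core stage then requires MAF
> 0.15 (strict), missing rate ≤ 0.05 (inclusive), PIC > 0.15 (strict);
the mixture of strict and inclusive bounds follows the thresholds'
standard statement verbatim, and each is unit-tested at its boundary.
Uniform genome coverage is achieved, when `bin_width` is set, by keeping
the single highest-PIC SNP per fixed-width bin per chromosome. The bin
width is deliberately a configuration knob: the source methodology reports
only resulting per-chromosome counts, not a procedure, so fixed-width
binning with a per-bin argmax is this package's design choice — it is
simple, deterministic, and reproduces "more SNPs where more chromosome"
proportionality.

**Genetic similarity.** For samples $a, b$:
$GS = NS/(NS + ND)$ with NS/ND the numbers of co-called loci with
identical/differing genotype classes. Missing-data handling is
pairwise-complete deletion (a locus missing in either sample contributes
to neither count); this matches the convention of the classical
similarity-matrix software used in this field. A heterozygote counts as
*different* from either homozygote — forced by the definition on genotype
classes. GS is computed for all $n(n-1)/2$ pairs via indicator
cross-products, so the 349-sample default cohort takes well under a
second.

**Threshold calibration (tail principle).** GS > 0.9 is the putative
derivation line, following international seed-federation practice. The
*indisputable* line is calibrated from positive controls — pairs of the
same variety grown at different sites, which bound the within-variety
similarity attainable in practice. The threshold is the minimum control
GS floored to two decimals ("tail principle"): a floor, not a round,
because the threshold must not exceed any observed within-variety value.
The floor carries a 1e-9 epsilon against binary representation of values
like 0.97. Pairs at or above the calibrated threshold are indisputable;
roles (IV vs. EDV) are assigned by registration year — earlier year is
the initial variety — and only when both years are known and unequal.
Equal-year or unregistered pairs keep `basis = "unresolved"`: the package
does not invent a tie-break the data cannot support.

**Core collection (least-distance stepwise sampling).** Within each
population, samples are ranked by the total count of differential
genotype classes against all other members (missing contributes nothing);
the smallest total indicates the closest kinship to the rest. The top
20% of the population's full size is kept, with the quota rounding rule
configurable (`half_up` default, `floor`, `ceil`) because published
per-population quotas in this domain are not reproduced by any single
standard rule (a 17-member population yielding 4 matches `ceil`, while
the larger populations match `half_up`/`floor`). Samples whose
own-population membership coefficient is below 0.8 are excluded up front
as heavily admixed. During the ranked walk, a candidate that is the
indisputable EDV of an already-selected sample (or the offspring of a
selected parent) is skipped for the next rank; conversely, if the initial
variety arrives after its EDV was already selected, the EDV is displaced
— derived varieties always give way, which is the only reading under
which no selected pair can remain an indisputable-EDV pair. Ties in the
ranking break lexicographically by sample id, making the output invariant
to input order.

**Minimal identification panel.** Greedy forward selection on
*discernibility*: the number of unordered sample pairs with at least one
co-called differing genotype class inside the panel. Step one takes the
locus with maximal single-locus discernibility; each later step adds the
locus resolving the most still-unresolved pairs; ties break by higher
PIC, then lexicographic locus id (determinism). Selection stops when the
panel's discernibility reaches that of the full candidate set — clone
pairs identical across all candidates are structurally unresolvable and
are reported as such rather than hidden. A missing call never
distinguishes a pair (conservative; a blank lane on a fingerprint gel is
uninformative). `exhaustive_panel()` enumerates all subsets on small
instances as an independent optimality oracle; the test suite checks on
200 random instances (≤ 12 samples × ≤ 10 loci) that greedy always
attains the exhaustive maximum. Greedy size-minimality is *not*
guaranteed in general (set-cover is NP-hard); the package guarantees
maximal discernibility and determinism, not provable minimality.
Fingerprints are per-sample strings over the panel (`0`/`1`/`2`/`N`,
i.e. class XX / XY / YY / missing).

## The simulator: what it emulates, and what it does not

`simulate_cohort()` generates validation cohorts with the structure the
analysis assumes:

- ancestral allele frequencies ~ Uniform(0.05, 0.95); subpopulation
  frequencies from the Balding–Nichols model
  $p_k \sim \mathrm{Beta}\!\big(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\big)$,
  so $\mathrm{Var}(p_k) = F\,p(1-p)$ — the `fst` knob has its textbook
  meaning and is verified by a frequency-variance recovery test;
- founders draw Binomial(2, $p_k$) genotypes per locus (Hardy–Weinberg
  within populations; tested via mean Ho ≈ mean GD);
- admixed individuals (6% by default, matching the ~20-of-349 admixture
  rate typical of such germplasm panels) draw from a 50/50 mixture of two
  populations' frequencies and carry membership coefficients below 0.8;
- derived varieties are genotype-class copies of a founder re-mutated
  per locus with probability 0.02 — class-level resampling, not
  allele-level, because GS operates on classes — so
  $\mathbb{E}[GS(\text{parent}, \text{EDV})] = 1 - m$; registration years
  are assigned so the parent is always earlier;
- positive controls are copies at rate 0.01, labelled via
  `control_group`, registered as landraces (same variety twice, no
  separate registration);
- missingness is MCAR at 2%; loci sit ≥ 400 bp apart on 15 chromosomes
  except for a configurable number of planted close pairs (default 10)
  that exercise the flanking filter.

Defaults (population sizes 159/72/51/50/17, six control pairs, twelve
derived pairs, 1000 loci) mirror the cohort scale this methodology was
developed on. What the simulator does **not** emulate: linkage
disequilibrium (loci are independent), genotyping error beyond the clone
mutation model, informative missingness, pedigree depth beyond single
parent–copy links, and selection/breeding structure. Passing tests
therefore demonstrate the pipeline's arithmetic and decision rules under
the stated population-genetic model, not robustness to correlated markers
or systematic genotyping artifacts on real data.

## Numerical and degenerate-input choices

- All statistics exclude missing calls from denominators; a locus or pair
  with an empty denominator yields a flagged `NA` plus a warning, never 0.
- The two-decimal floor in calibration uses `floor(x * 100 + 1e-9) / 100`.
- Sample-order invariance everywhere; all ties (ranking, panel selection)
  break lexicographically.
- A population left with < 2 eligible samples yields its sole member (or
  nothing) with a warning; an empty core-SNP set is a warning from
  `select_core` but an error in `run_pipeline`, where continuing would be
  meaningless.
- Multi-allelic VCF records are skipped with a message by default
  (`biallelic_only = TRUE`) or rejected; duplicate coordinates are always
  an error.
- Problem sizes in the test suite: the full-scale checks use the default
  349 × 1000 cohort (seconds, via matrix cross-products); optimality
  oracles run on 200 random ≤ 12 × ≤ 10 instances where exhaustive
  enumeration is exact.

## Known limitations

- GS has no sampling-uncertainty quantification here (no bootstrap CI);
  with several hundred core SNPs the binomial standard error of GS near
  0.97 is ~0.005, which is why two-decimal calibration is sensible, but
  panels much smaller than ~300 loci would make threshold comparisons
  noisy.
- The EDV direction (who derived from whom) rests entirely on
  registration years; biological derivation can precede registration
  order in principle.
- The greedy panel is optimal in discernibility, not guaranteed minimal
  in size.
- The flanking-uniqueness proxy can only see variants present in the call
  set; rare flanking variation absent from the cohort is invisible to it.

## A complete run

```{r, eval = FALSE}
library(snpEDV)
sim    <- simulate_cohort(sim_config(seed = 1))
report <- run_pipeline(sim$geno, sim$meta, out_dir = "edv_out")
report                      # stage counts, calibrated threshold, panel size
truth_eval(report$edv_calls, sim$truth)   # clone recovery vs. truth table
```
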