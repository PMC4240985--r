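---
title: "Inferring homoploid hybrid parentage from multilocus sequence identity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring homoploid hybrid parentage from multilocus sequence identity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybparent)
```

## The problem

Many cultivated ornamental plants arose by hybridization among several
wild congeners without any change in ploidy. Tree peony cultivars are the
motivating case: a diploid cultivated complex maintained by propagation,
whose wild relatives form two well-defined subsections of shrubby species.
Because hybrids are homoploid, each cultivar carries two alleles at every
nuclear locus — each traceable to some wild species — plus a single,
maternally inherited chloroplast genome. `hybparent` implements the
inference chain that turns this signal into parentage statements:

1. **Marker screening.** Per-locus informativeness statistics (variable
   sites, parsimony-informative sites, nucleotide diversity per site
   $\pi$), a $\chi^2$ test of base-composition heterogeneity among taxa,
   and a MaxChi-style scan for intragenic recombination. The most
   informative loci are retained for parentage work.
2. **Cyto-nuclear discordance.** A concatenated nuclear tree and a
   chloroplast tree for the wild panel; species monophyly and
   Robinson–Foulds (RF) distance quantify the incongruence that signals
   introgression and chloroplast capture among wild species.
3. **Parentage assignment.** Cultivar clone sequences are dereplicated
   into allele haplotypes, matched at 100% identity against the wild
   reference panel, the maternal donor is assigned from the chloroplast
   haplotype, and the minimal set of species explaining all matched
   alleles is found by exact set cover.

A seeded synthetic-data generator produces wild panels and hybrid
cultivars with recorded truth, so that every step can be scored against a
known answer.

## The statistics

**Variable and parsimony-informative sites.** A column is *variable* if it
shows at least two distinct non-missing states; it is
*parsimony-informative* if at least two states each occur in at least two
rows. Gaps and `N` are missing data: excluded per column for site counts
and pairwise for distances and $\pi$. A strict five-state treatment of
gaps was considered and rejected: the generator never emits gaps, and on
real alignments indel columns mostly track alignment uncertainty rather
than substitution signal.

**Nucleotide diversity.** For rows $i<j$ with $c_{ij}$ comparable sites
and $d_{ij}$ differences,
$\pi = \binom{n}{2}^{-1} \sum_{i<j} d_{ij}/c_{ij}$; pairs with no
comparable site are dropped, and an alignment in which no pair is
comparable is an error rather than a silent zero.

**Base-composition heterogeneity.** The taxa × base count table (missing
states excluded) is tested with the classical Pearson $\chi^2$; bases with
zero column totals are dropped before computing
$df = (\text{taxa}-1)(\text{bases}-1)$, which avoids degenerate expected
counts, and rows with no countable base are excluded with a warning. Under
homogeneous simulation the test rejects at close to the nominal 5% rate
(the acceptance suite checks the 1000-replicate rejection rate against
[0.03, 0.07]).

**MaxChi-style recombination scan.** For each sequence pair, candidate
breakpoints are the pair's observed mismatch positions; at each candidate
the mismatch counts in half-windows left and right are contrasted with a
2×2 $\chi^2$ (df 1). Restricting candidates to mismatch positions is what
the statistic's geometry implies — the maximum is always adjacent to a
mismatch — and it keeps the multiple-testing burden proportional to
signal. p-values are Bonferroni-corrected over pairs × candidates within
the locus; this is deliberately conservative, which the clonal-null
false-positive check (≤ 10% of datasets at $\alpha = 0.05$) confirms with
a wide margin. The default window is 200 bp (100 bp per side); detection
of a constructed recombinant junction is tested with window 300 on
sequence pairs ~12% divergent. Only this one scan statistic is
implemented; multi-method recombination screens remain the job of
dedicated external software.

**Marker ranking.** "Most informative" is defined here, deliberately and
explicitly, as: parsimony-informative % first, then variable %, then
aligned length (longer first), then locus id. Any monotone informativeness
score would do; PI% is the quantity that actually drives resolution in
parsimony- and split-based analyses.

## Tree inference tier

The package's tree tier is intentionally desk-scale: p- and JC69
distances with pairwise deletion, neighbour joining, Fitch small parsimony
with exact enumeration up to 9 taxa (the $(2n-5)!!$ wall) and NNI
hill-climbing with restarts beyond, and nonparametric bootstrap (default
100 replicates, seed mandatory in pipeline mode). Likelihood and Bayesian
machinery are deliberately out of scope: the downstream parentage logic
consumes topological statements (monophyly, RF distance), which this tier
already recovers with ≥95% bootstrap under clean simulated signal.

Numerical choices: JC69 distances saturate at $p \ge 0.75$; such pairs
are capped and flagged rather than propagated as `NaN`. Negative NJ
branch lengths are clamped to zero with the deficit moved to a sibling
edge, and a warning identifies the clamp. Missing states in Fitch are
fully ambiguous `{A,C,G,T}` and contribute no change. Bipartition
comparisons are on unrooted trees; rooting is display-only.

## The parentage model

**Dereplication.** Cultivar sequences arrive as 8–16 cloned reads per
locus. Identical clones collapse into haplotypes with counts; haplotypes
below `min_count = 2` are discarded as presumptive PCR/sequencing
artifacts *unless* they exactly match a reference allele (the rescue
rule), and the most frequent haplotype is always kept. The default of 2
balances artifact suppression against losing a genuinely rare second
allele; raising it costs recall under low clone counts.

**Matching.** The evidentiary standard is 100% identity (`max_mismatch =
0`), matching the definition used when allele sharing between cultivar
and wild species is read off directly. An allele identical to alleles of
several species yields a multi-species cell; an allele matching nothing
is tallied as *unexplained* and never invents a parent. A tolerance mode
(nearest species within `max_mismatch`) exists for degraded data; it is
off by default.

**Maternal assignment.** The chloroplast is one linked haplotype; the
species minimising p-distance is the maternal donor. Ties are broken by
the species matching at the most nuclear markers for that cultivar, then
lexically — joint evidence first, determinism second. Distances above a
ceiling (default 0.01, i.e. 10 mismatches/kb — the knob that
operationalises "nearly identical") leave the cultivar unassigned rather
than guessing.

**Parental sets.** Each cultivar's parental set is the smallest species
set that contains the maternal donor (when assigned) and hits every
nonempty marker cell — minimum set cover with cells as subsets. Cover
ambiguity is resolved by total marker coverage and then lexical order,
and all co-optimal covers are reported. Because any member of a
multi-species cell satisfies it, a species whose every contribution is
shared with another parent is correctly *discounted* — the same
parsimony-of-parents logic that excludes a candidate wild species whose
apparent contribution is fully shadowed by another. Exact search is used
up to 15 candidate species (subset enumeration by increasing size), with
a greedy fallback beyond; the exact branch is verified against full
subset enumeration in the test suite.

## The synthetic-data generator

The generator is the package's benchmark instrument, and its defaults
*are* the study conditions the analysis is designed for:

* 9 wild species on a pure-birth (Yule, rate 1) ultrametric tree, split
  into two subsections by the root; within-species structure is 2
  accession rows per locus carrying shallow variation (0.002/site).
  How many wild alleles per species per locus exist in real panels is
  essentially unreported (wild accessions are typically sequenced
  directly because they show no polymorphism), so the depth is a free
  knob with a deliberately shallow default.
* 25 nuclear loci, lengths uniform on 322–3656 bp, JC69 (K2P optional)
  with per-locus rates drawn from 0.008–0.025 per site per unit branch
  length — calibrated so the variable-site fraction falls in roughly the
  3.6–18.8% band typical of fast intron markers; the chloroplast is a
  single linked 3700 bp haplotype at a lower rate (0.006), mirroring its
  uniparental inheritance and lower diversity. Indels are not simulated;
  gap handling is specified for real input only.
* Wild species always end with pairwise-distinct chloroplast haplotypes
  (duplicates arising on very short branches receive two private
  substitutions): the wild panel is modelled as having distinguishable
  chloroplast genotypes, which is what makes maternal assignment a
  well-posed benchmark.
* 47 cultivars, each a first-generation homoploid hybrid: a parental set
  of 2–3 species from a 5-species pool (taken from the larger
  subsection), the maternal donor drawn with weight 0.7 on the pool's
  first species (one dominant chloroplast donor, as observed in real
  cultivar cohorts), chloroplast copied from the maternal species,
  and at each locus two alleles copied from accession rows of recorded
  parental species. Post-origin mutation (default 0.001/site) and
  per-clone error (default 5e-4/site, 8–16 clones) are separate knobs;
  zero-noise settings give exact-copy closure, the anchor for recovery
  benchmarks.
* Chloroplast capture among wild species is available as an explicit
  event (donor's haplotype copied over the recipient's, nuclear loci
  untouched, event recorded) or as a per-species probability.

What the generator does **not** emulate: alignment error and indels,
multi-generation pedigrees and backcrossing, intra-locus recombination in
cultivars, lineage sorting of ancestral nuclear polymorphism, and
read-level sequencing artifacts beyond iid per-site clone error. Passing
recovery benchmarks therefore demonstrates the correctness of the
inference machinery under the model's assumptions, not robustness of the
conclusions to every failure mode of real data.

## What the benchmarks compute

Problem sizes were chosen so the whole suite runs in minutes on one CPU:
the headline recovery run uses the full 9-species / 25-locus / 47-cultivar
configuration at zero noise; oracle-equivalence checks use 100 random
alignments (≤6 rows × ≤50 columns), exhaustive parsimony up to 7 taxa, and
set-cover enumeration up to 12 species; NJ consistency uses 50 random
trees (n ≤ 12); the scan statistics use 1000 homogeneous replicates
($\chi^2$) and 200 clonal replicates (MaxChi).

Under those conditions the package recovers, from scratch: a cohort
parental union of exactly the 5 pool species with precision = recall = 1,
maternal accuracy 1, and a dominant maternal donor; RF(cp, nuclear) > 0
with a broken chloroplast clade after one injected capture event while
every species stays monophyletic on the nuclear tree with ≥95% bootstrap —
the computational restatement of cyto-nuclear discordance. The
`scripts/acceptance.R` script recomputes all of these quantities at run
time for any seed.

One caveat stated explicitly: full recall of the parental union requires
each true parent to contribute at least one *private* allele among the
selected loci. When a parent's every contribution is verbatim-shared with
another species (common in very small simulations with short loci), the
minimal-cover logic discounts it — by design. The acceptance runs verify
the private-allele condition on the generated dataset rather than assuming
it.

## Known limitations

* Strict identity matching is brittle to any post-origin mutation at a
  locus where the cultivar carries no other matching allele; the
  unexplained-allele tally is the honest signal of this, and the
  tolerance mode the pragmatic workaround.
* The NJ/MP tier is not a substitute for model-based phylogenetics on
  hard datasets (rate heterogeneity, saturation); it is the desk-scale
  instrument for topological checks on clean or simulated data.
* Set-cover parsimony can under-report true parents (see the private-
  allele caveat) and reports co-optimal covers rather than forcing one.
* The greedy cover fallback (>15 candidates) has no minimality
  guarantee; with ≤9 wild species the exact branch always runs in
  practice.
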