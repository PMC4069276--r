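---
title: "Half-sib phasing from opposing homozygotes: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Half-sib phasing from opposing homozygotes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halfsibs)
```

## The statistical object

A paternal half-sib family — one sire, many offspring, each out of a
different dam — carries far more linkage information than its size
suggests. The package exploits a single Mendelian fact: a locus at which
two individuals are homozygous for opposite alleles (genotypes 0 and 2;
an *opposing homozygote*, OH) cannot occur between parent and offspring
except through genotyping error. Three consequences drive everything:

1. **Relationship separation.** Under Hardy–Weinberg with
   reference-allele frequency $p_k$ at locus $k$, the per-locus OH
   probability is $2p_k^2q_k^2$ for unrelated pairs, $p_k^2q_k^2$ for
   half sibs and $p_k^2q_k^2/2$ for full sibs ($q_k = 1-p_k$). The
   half-sib case: the two offspring draw the *same* sire strand with
   probability $\tfrac12$, in which case an OH is impossible, and
   different strands otherwise, in which case the probability is the
   unrelated one. Genome-wide sums of these give `expected_oh()`, and
   the factor-two identity `e_unrelated = 2 * e_halfsib` holds for any
   frequency vector. The acceptance cutoff for the frequency-based
   pedigree criterion is placed 90% of the way from the half-sib toward
   the unrelated expectation; the source description of that rule is
   ambiguous ("90% of the average difference"), and this reading is the
   only one that accepts true half-sib pairs while rejecting unrelated
   ones.
2. **Informative SNPs.** Within a family, a SNP with an OH pair proves
   the sire heterozygous there; the homozygous offspring then reveal
   which sire strand they inherited.
3. **Parentage exclusion.** The minimum-OH candidate below a mismatch
   allowance (default 1% of markers, a conventional genotyping error
   budget) is the parent; ties are reported, never broken silently.

## Block construction

`build_blocks()` scans informative SNPs in map order. The first one
anchors the family: homozygote-0 carriers to group 1, homozygote-2 to
group 2 (the labels are exchangeable — every downstream statistic is
invariant to the global 1↔2 swap, and squared correlations are used for
scoring precisely because squaring absorbs the swap). At each later
informative SNP the two homozygote classes are mapped onto the groups in
the orientation that forces the fewest already-labelled individuals to
switch, recombination between adjacent SNPs being a priori unlikely;
cost ties keep the previous orientation.

A labelled individual whose homozygote class contradicts its group is a
*candidate* switch. It is committed — becoming a recombination event —
only after it persists at the individual's next informative observation
(`persistence = 1`, configurable; the source description says only
"during the next steps"). A lone contradiction flanked by the original
group on both sides is recorded as a genotyping error and the label is
unchanged. A candidate still pending at the chromosome end is committed,
since no later observation could contradict it.

**Event attribution.** A committed switch's new segment begins at the
interval following the last SNP where the old group was actually
*observed* for that individual — the same convention used when a switch
spans a run of undetermined labels. Besides determinism, this choice
concentrates the signature of a misplaced map SNP at that SNP instead of
smearing it across each individual's observation schedule, which is what
makes `flag_map_errors()` work.

**Known limitation.** The orientation vote uses current labels, which
are stale for an individual not observed since before its own crossover.
When several members recombine within a short window, the vote can tip
at one SNP and pool their switches there, or a reverted pending switch
can cancel a real event. Measured on 600-SNP, 1-Morgan families of
eight, the per-individual event count and placement agree with an
idealised sequential oracle for 79–100% of individuals (mean 94% over 20
seeds); aggregate quality is what the R² ≥ 0.9 acceptance criterion
certifies. This behaviour is inherent to the greedy minimum-switch
formulation, not a defect of this implementation.

## Sire inference, offspring phasing, imputation

For strand $s$ and SNP $k$, `infer_sire_haplotypes()` averages the
genotypes of the offspring labelled $s$ at $k$. The group mean equals
(paternal allele) + (mean dam contribution); the dam term lies in
$[0,1]$, so a mean below 0.5 *proves* paternal 0 and above 1.5 proves
paternal 1. Means in between — including exactly 1 — are uncalled (9).
"Round to nearest integer" would call such sites, but a rounded 1 has no
single-strand interpretation, so the thresholds deliberately trade call
rate (roughly 50–70% at intermediate frequencies and family size 8) for
a call accuracy that is exactly 1 on error-free data. Both thresholds
are arguments.

`phase_family()` reads each offspring's paternal allele off the sire
strand its block label selects; an offspring homozygote that contradicts
the assigned allele voids the call (logged) rather than overriding the
block, since a local genotyping error should not rewrite a haplotype.
Maternal = genotype − paternal wherever both are defined, which makes
the conservation identity paternal + maternal = genotype hold by
construction at every fully-called site.

`impute_paternal()` re-blocks the family on the low-density panel,
orients that blocking against the high-density sire scaffold (labels are
exchangeable per family, so the low-density groups are matched to the
scaffold strands via the panel's own strand estimates and swapped if the
crossed mapping agrees better — omitting this step halves accuracy at
heterozygous sites whenever the two blockings anchor on opposite
orientations), expands labels between low-density SNPs that agree, and
fills alleles from the scaffold. High-density SNPs inside a
recombination interval, or beyond the terminal low-density markers, stay
uncalled: the package never guesses a breakpoint position.

## The simulator and what a green test establishes

`simulate_halfsib()` drops gametes through a stated world: per-SNP
frequencies Uniform(0.1, 0.9) (a polymorphic SNP-array ascertainment),
sire strands and dam alleles independent Bernoulli draws, crossovers
Poisson per Morgan without interference (Haldane), positions uniform
over intervals, equally spaced SNPs, genotyping errors replacing a cell
with a uniformly different genotype, missingness applied last. One seed
fixes the full output. It does **not** model linkage disequilibrium
among founder haplotypes, ascertainment structure, pedigree depth,
selection, or interference — so green tests certify algorithmic
correctness under Mendelian transmission, not robustness to every
artefact of real arrays.

Two regimes are used deliberately:

* **Block/phasing/imputation tests** use one chromosome, 1 Morgan,
  2,000 SNPs — the density regime where block detection and imputation
  are claimed accurate ($R^2 > 0.9$ for families of ≥ 8), and the
  regime the acceptance report reproduces.
* **OH-statistic and pedigree-reconstruction tests** use
  `unlinked = TRUE`: every SNP's paternal transmission an independent
  coin flip, i.e. a sparse genome-wide parentage panel in linkage
  equilibrium. This matters: on a *single* 1-Morgan chromosome two half
  sibs share almost all or almost none of their paternal gamete, so the
  half-sib and unrelated OH distributions do not separate at all; even
  on a realistic linked genome of 29 one-Morgan autosomes the
  shared-fraction variance leaves roughly a quarter of 5-family
  replicates imperfectly recovered. The relationship separation the
  method relies on is a genome-wide, effectively-unlinked-marker
  phenomenon, and the simulator states that world explicitly rather
  than pretending a single chromosome behaves like a genome.

Map-error detection is likewise a *dataset-scale* capability: a single
displaced SNP is informative in only about a third of families of
eight, so its test world uses 15 families of 16 at 600 SNPs/Morgan,
where flagging is stable across seeds. The flagging baseline is the
median rate over intervals with at least one event — the profile's
resolution floor — because the plain median interval rate is zero on
any realistic map; an interval is flagged only when its rate exceeds
`rate_factor` times that floor *and* at least `min_families` families
show an event there independently.

## Numerical conventions

* Midpoint cutoffs round with R's `round()` (half-to-even), matching
  the worked example that fixes this convention.
* Ward clustering uses `hclust(method = "ward.D")` on
  `dist(method = "manhattan")` over OH-matrix rows: the Lance–Williams
  Ward update applied directly to the Manhattan matrix, reconciling the
  named metric and linkage.
* Group labels in `reconstruct_families()` are ordered by smallest
  member id; clusters of ≤ 2 members are terminal (a 2-bisection is
  meaningless), labelled if they satisfy the criterion and otherwise
  left unassigned and flagged.
* The regression separation criterion ships with **no default
  coefficients**: the only published ones were fitted to a specific
  sheep population and are known to transfer poorly.
* Positions are 1-based base pairs; algorithms use only their order.

## Limitations

Dams are never reconstructed, maternal haplotypes never imputed at
high-density-only loci, and no likelihood or HMM machinery is involved:
the method is deterministic, which is why identical seeds give
bit-identical pipelines and results are independent of thread count and
individual ordering (up to the documented label swap). Accuracy
degrades with family size below ~8, sparse maps, and pedigree errors —
a wrongly included individual inflates apparent recombination for the
whole family, which is exactly the diagnostic the recombination-based
pedigree criterion turns into a separation rule.
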