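---
title: "Simulating reference-genome divergence effects on SNP discovery and diversity estimation"
author: "refdivsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating reference-genome divergence effects on SNP discovery and diversity estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question the package addresses

Conservation projects for threatened species often lack a conspecific
reference genome and instead map their reduced-representation (GBS) or
whole-genome resequencing reads to the genome of a related species. The two
discovery paradigms react to reference divergence in opposite ways: a
tag-based caller (Tassel-style) discovers SNPs from differences *among* tag
pairs across individuals, so a more distant reference mostly costs mapped
tags and therefore SNPs; a pileup caller (mpileup/BCFtools-style) discovers
SNPs from differences *between* reads and the reference, so a more distant
reference inflates the raw SNP count with fixed interspecific differences.
What ultimately matters for management is whether the diversity summaries
computed from the two marker sets — nucleotide diversity ($\pi$),
individual heterozygosity ($H_S$) and pairwise relatedness ($R$) — stay
concordant with the conspecific-reference answer.

`refdivsim` rebuilds that whole measurement chain in silico, with known
ground truth: a pedigreed diploid population on a focal genome, a ladder of
diverged references, both sequencing strategies, a deterministic mapper,
both callers, the standard filter cascades, and the comparison statistics
(tag-set intersection, Spearman rank correlation, Mantel permutation
tests).

## The synthetic study conditions

`simConfig()` freezes the study conditions; every run is reproducible from
its integer seed.

* **Focal genome**: 1 Mb of i.i.d. sequence at GC 0.42 (avian-like). One
  scaffold; real chromosome structure is irrelevant to the mechanisms
  studied here.
* **Pedigree**: 30 individuals — 8 founders, 11 families of 2, where the
  first 4 families are founder couples and later families cross offspring
  of two distinct earlier families. This yields parent–offspring and
  full-sib pairs (expected additive relatedness 0.5), second-degree (0.25)
  and cousin-level pairs (0.125), and unrelated lineages (0), so the
  off-diagonal relatedness distribution is bimodal with graded structure in
  between. The design was chosen by a pre-hoc calculation on the expected
  relationship matrix: because the relatedness estimator uses sample allele
  frequencies (see below), every row of the raw matrix centres towards
  zero, deflating close-pair estimates by roughly the individuals' mean
  relatedness to the sample; designs dense in relatives push
  parent–offspring estimates well below 0.5, while designs dominated by
  unrelated pairs cap the achievable rank correlation between estimated and
  expected relatedness (mid-rank ties in the unrelated class dominate the
  rank variance). The default is the best compromise the calculation
  found; with it, parent–offspring pairs are recovered near 0.42 and the
  rank correlation sits near 0.88 — the residual bias is a property of
  sample-frequency genomic relationship matrices, not of the
  implementation.
* **Variants**: each site segregates in the founders with probability
  $\theta = 0.005$; founder alt-allele frequencies are uniform on
  $[0.05, 0.5]$ so the MAF filters keep a non-trivial fraction. Sites are
  inherited independently (no linkage map); consequences are discussed
  under *Limitations*.
* **Divergence ladder**: substitution proportions 0.005 / 0.035 / 0.07
  standing in for congeneric, confamilial and conordinal references. The
  true genome-wide divergences of real reference ladders are not published;
  these presets were chosen so the stand-in mapper reproduces the
  qualitative ordering of cross-species alignment rates, and they are
  configurable. Substitutions always change the base; small indels
  (1–3 bp) are added at a per-site rate that scales linearly with
  divergence and equals `refIndelRate` ($2\times10^{-4}$) at the middle
  rung — a flat indel rate across a 1–69 Myr ladder would be biologically
  implausible and would make cross-rung mapping losses hinge on Poisson
  noise in indel counts rather than on divergence.
* **GBS**: ApeKI recognition motif `GCWGC` (palindromic, so a forward scan
  finds both strands); 64 bp tag pairs flanking each cut site; reads per
  locus per individual Poisson with mean 15 (matching the empirical
  per-individual depths of published GBS datasets this design emulates);
  per-base error $10^{-3}$ (Q30).
* **Resequencing**: 2×150 bp mates on 350 bp fragments placed uniformly on
  a uniformly chosen haplotype, giving approximately Poisson coverage with
  mean 15; same error model.

## Mapping

`mapCollection()` is a deterministic seed-and-extend aligner: exact k-mer
seed hits propose candidate placements, each candidate is extended
*ungapped* over the full query on both strands and scored by Hamming
distance, and a hit is accepted when its mismatch count is at most
$\lceil 0.10\,L \rceil$. The best hit wins; equal-best hits at distinct
placements mark the query ambiguous, and ambiguous queries are excluded
downstream (this protects the callers from paralog-style artifacts).
Alignment rate is the fraction of queries with a unique accepted hit.

Sensitivity is exhaustive by construction: a first round uses disjoint
seeds of length $\min(\mathrm{seedLength}, 12)$; if the best hit found is
not certified by the pigeonhole bound (with $s$ disjoint seeds every hit
with fewer than $s$ mismatches shares a seed), a second round re-collects
candidates with $k = \lfloor L/(\mathrm{maxmm}+1)\rfloor$ disjoint seeds,
which guarantees every acceptable hit is seen. The mapper is therefore
*provably identical* to a brute-force scan of every offset on both strands
— and the test suite verifies that equivalence against an independently
coded brute-force oracle on random 10 kb genomes.

Ungapped extension is a deliberate simplification: reference indels simply
depress the mapping rate, qualitatively matching cross-species mapping
loss, and they keep the oracle exact. Tag pairs are mapped as two
independent queries; a pair counts as mapped only when both mates map
uniquely to the same scaffold within 1 kb.

## SNP calling

**Tag-wise (GBS).** Uniquely mapped tag pairs are grouped by mapped
coordinates; distinct tag-pair sequences with population-wide read count
below 10 are dropped (the Tassel-style minimum tag count — note this
operates on sequence identities, so an individual whose variant tag also
carries a rare private variant can lose that allele, a realistic dropout
mechanism). Within a locus, tag sequences are compared position by
position; the reference base is never consulted. A site is emitted when at
least two alleles segregate among individuals, minor-allele frequency is at
least 0.05, and at least 75% of individuals have a tag at the locus.
Genotypes come from each individual's own tag alleles (both seen =
heterozygote); the locus major allele plays the role of the "ref" allele in
the output, and per-call depth is the individual's tag count at the locus.

**Pileup (resequencing).** Uniquely mapped reads are stacked on the
reference; per site and individual the genotype is the maximum-posterior
call under a symmetric-error binomial read model with a uniform prior over
{ref/ref, ref/alt, alt/alt} (ties resolve towards fewer alt alleles; zero
depth is missing). A site is emitted when any individual's call differs
from the reference base. The site's alt allele is the non-reference base
with the highest population read count; further non-reference bases with
substantial support (≥ 10% of the site's reads, minimum 2) raise the
allele count above 2 — such genuinely multi-allelic sites (e.g. a focal
polymorphism superimposed on an interspecific substitution) are retained at
discovery and removed by the biallelic filter, as in the real pipelines.

## Filtering

Both cascades run per-site filters first — biallelic; mean call depth ≥ 5
(GBS) or > 10 (resequencing); ≤ 10% missing genotypes per site ("90% of
SNPs shared amongst individuals" is read as per-site missingness);
resequencing additionally requires MAF > 0.05 (GBS applied its MAF rule at
discovery) — then distance thinning (one SNP per 64 bp for GBS, per 150 bp
for resequencing: the tag and read lengths), then LD pruning at $r^2 > 0.8$
against the last 1000 *retained* sites.

Two deliberate choices here. First, the LD window counts retained sites:
counting candidate sites instead makes the operation non-idempotent
(removals pull previously out-of-window pairs into range on a re-run).
Second, pruning runs *after* thinning: pruning only removes sites, so the
spacing guarantee survives it, and with the LD pass last both
post-conditions — minimum spacing, and no retained in-window pair above the
threshold — hold on the final set by construction. (With the opposite
order, thinning exposes new in-window pairs; in this generator, where
sites are unlinked and $r^2$ is distance-independent, such pairs
occasionally exceed the threshold by chance.) Both post-conditions are
audited on every run and the cascade is idempotent; a per-stage audit table
is attached to the result.

## Diversity and relatedness

* **Per-site $\pi$** is the unbiased pairwise-difference estimator
  $2 n_0 n_1 / (n(n-1))$ over called allele copies.
* **$H_S$** is the proportional excess of observed over expected
  heterozygous genotypes per individual,
  $(O_i - E_i)/E_i$ with $E_i = \sum_k 2 p_k (1-p_k)\, n_k/(n_k-1)$ over
  the individual's callable sites. This is $-F$ in the method-of-moments
  sense: a plain heterozygote proportion can never be negative, whereas
  allele dropout against distant references drives this statistic negative,
  matching how the statistic behaves in practice.
* **Relatedness.** Off-diagonals are a dosage GRM,
  $M_{O,ij} = \mathrm{mean}_k\, (x_{ik}-2p_k)(x_{jk}-2p_k) / (2p_k(1-p_k))$
  over sites non-missing in both individuals (pairs sharing fewer than 50
  sites are flagged low-confidence). The diagonal cannot use called
  dosages — genotyping noise would cancel — so it uses read-ratio dosages
  $\hat x = 2a/d$; under Hardy–Weinberg the binomial read sampling inflates
  $E[(\hat x - 2p)^2]/(2pq)$ by exactly $1/d$ per site
  ($\mathrm{Var}(\hat x \mid \text{het}) = 1/d$ and
  $P(\text{het}) = 2pq$), and the estimator subtracts
  $\mathrm{mean}_k(1/d_{ik})$. This is a transparent, testable
  implementation of depth-aware relatedness estimation rather than a
  reproduction of any particular tool's internals.
* **Scaling.** $M_S = D\,M_O\,D$ with $D_{ii} = 1/\sqrt{M_{O,ii}}$, so
  every self-relatedness equals 1 exactly; a non-positive diagonal entry is
  an error naming the offending individual.

## Cross-reference comparison

The tag-share statistic intersects the *sets of tag-pair sequence
identities* that mapped uniquely in two runs (coordinates are not
comparable across references) and reports
$100\,|A \cap B|/|A|$ with $A$ the run under comparison — the only
denominator consistent with published tag-share tables, where the shared
percentage of a distant-reference run exceeds what the conspecific-set
denominator would allow. A run compared with itself yields exactly 100.
Note a structural property of the simulation: because the focal reference
*is* the exact source genome, essentially every tag that maps to a diverged
reference also maps to the focal one, so cross-reference shared percentages
sit near 100 rather than declining as they do with real assemblies — real
declines are driven by assembly incompleteness and repeat structure that
this generator deliberately does not model. The mapped-tag *counts*, not
the shared percentages, carry the divergence signal here.

Spearman's $r_S$ is the Pearson correlation of mid-ranks with the
two-sided large-sample t approximation. The Mantel test correlates
off-diagonal elements, permutes rows and columns of the second matrix
simultaneously, and reports the one-sided $p = (1 + \#\{perm \ge obs\}) /
(B + 1)$; with identical matrices and $B = 999$, $p = 0.001$ exactly
unless a non-identity automorphism ties.

`runComparison()` assembles everything: one simulation, both pipelines
against the focal and all diverged references, and a report with one row
per mode × reference. Mixed-model repeated-measures testing of $H_S$ is
deliberately out of scope; the report carries descriptive mean differences
against the focal run instead.

## Numerical and degenerate-input choices

Greedy first-kept tie-breaking in thinning and pruning; genotype-likelihood
ties resolve towards fewer alt alleles; undefined correlations (constant
dosage vectors, fewer than two complete pairs) never trigger LD removal;
$\pi$ is skipped (NA) below two called alleles; $H_S$ is NA for an
individual with no callable site; the relatedness estimator refuses
monomorphic input (a filter-contract breach); Spearman on a constant
vector warns and returns a flagged NA; tag loci whose windows run off the
scaffold are skipped with a message. Coordinates are 1-based throughout
the R interfaces (the Biostrings/IRanges convention) and only the C++
kernels work 0-based internally.

## Problem sizes used by the tests

Module tests run on 20–200 kb genomes with 4–10 individuals. The
acceptance-style checks run the full study conditions — 1 Mb, 30
individuals, seeds 1–5 — once per seed and share the runs across checks;
one full run takes a few minutes on a single core. The acceptance script
(`scripts/acceptance.R`) recomputes the two analytic headline quantities
(unit diagonal after scaling; 100% self tag-share) from scratch at 150–250
kb scale in under a minute.

## Limitations

* Sites are unlinked (no recombination map, no coalescent): LD pruning
  rarely removes anything beyond duplicated signals, and $r^2$ carries no
  spatial decay.
* Divergence is homogeneous along the genome; real genomes mix conserved
  and fast-evolving regions, which strengthens the correlation between
  mappability and local diversity. Accordingly, the decline of mean $H_S$
  across the ladder is driven here only by threshold-crossing allele
  dropout: it is clear at the most distant rung but weak and
  sign-unstable at the close rungs — at 0.5% divergence a 64 bp tag sits
  far below the 7-mismatch acceptance bound, and mild dropout moves
  $O_{het}$ and $E_{het}$ (through the sample frequencies) in the same
  direction, so the intermediate rung can even drift slightly upward. A
  strictly monotone mean-$H_S$ ladder should therefore not be expected
  from this generator, only the distant-rung drop.
* The focal reference is the exact source genome: no assembly gaps,
  repeats or errors, hence self-vs-cross tag-share percentages stay near
  100 and mapping to the focal reference is essentially perfect.
* Ungapped alignment; reference indels lower mapping rates rather than
  producing gapped alignments.
* The sample-frequency GRM deflation discussed above bounds how exactly
  pedigree relatedness can be recovered from a related sample; scaling
  restores the diagonal but not the off-diagonal bias.
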