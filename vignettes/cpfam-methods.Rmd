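---
title: "Methods: models, parameters and design choices in cpfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in cpfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cpfam analyses the evolution of a tandemly expanding gene family — written
around the papain-like cysteine proteases that constitute the group 1
allergens of astigmatic mites — across a set of annotated genomes. This
vignette documents the models and procedures behind each stage, the
parameters that matter, the numerical conventions, and the places where the
design was genuinely open and a choice had to be made. It states no
empirical result beyond what the package's test suite and acceptance script
themselves compute.

## Homology search

Family membership is decided by optimal local alignment (Smith-Waterman
with affine gaps) against a panel of reference allergens. The scoring
defaults are the classic protein-search settings: BLOSUM62, gap open 11,
gap extension 1, with a gap of length $k$ costing $11 + k$. Identity is
`matches / alignment_length` with gap columns counted in the denominator
(the BLAST convention), and the membership rule is identity ≥ 0.30 —
a published "approximately 30%" implemented as a hard threshold, with
near-threshold cases (within 0.02) flagged in the output for audit.

Significance filtering uses no E-value. Instead a raw-score threshold is
calibrated on shuffled decoys: sequences drawn from the proteome under
study are residue-shuffled and aligned to randomly chosen references, and
the 99.9th percentile of 1,000 decoy scores becomes the acceptance
threshold. This is deterministic given a seed and avoids Karlin-Altschul
parameter estimation entirely.

Co-optimal alignments are resolved by a fixed tie chain — earliest subject
end, then earliest query end, then shortest alignment (the traceback
restarts at the first zero-score cell) — so results are reproducible to the
byte and the brute-force enumeration oracle in the tests can apply the
identical chain.

A position-specific scoring model provides the cross-validation channel:
per-column log2-odds from pseudocount-smoothed residue frequencies against
a uniform background (pseudocount weight 1; as the weight grows the scores
collapse to the background, which the tests assert), scanned as the best
ungapped placement of the profile along each protein.

## Synteny: tandem and proximal arrays

Gene order on a scaffold is taken purely from start coordinates, strand
ignored. A "spacer gene" is any annotated gene not in the identified family
set. Maximal runs of family genes in which consecutive members are
separated by at most 9 spacers form arrays: a run is a tandem array (TAG)
only when every gap is zero; a run with any positive gap is a proximal
array (PAG); everything else is a singleton. Every family gene thus lands
in exactly one class, which the tests assert as a partition property. A
mixed run (some gaps zero, some 1–9) is deliberately classified PAG, and an
array of $n$ genes contributes $n$ to the "arrayed" count in summary
tables (members are counted, not arrays).

## Gene-decay detection

A lineage-specific loss is only credible when the surrounding synteny
survives. For each single-copy ortholog cluster and each species without a
member, the cluster's neighborhood (10 genes each side) in a reference
species is searched for flanking genes with a reciprocal-best ortholog in
the missing species; an event is `anchored` when at least one flank per
side anchors and the two anchors are within a window-sized gene span on one
scaffold.

Anchor orthology uses identity defined as local-alignment matches divided
by the length of the shorter protein, at threshold 0.5. A plain
local-alignment identity was tried first and rejected: between unrelated
proteins the optimal local alignment is typically a short segment with
inflated identity (6/7 matches = 86%), which a coverage-normalized identity
suppresses while true orthologs, aligning end to end, are unaffected.

## Alignment and phylogeny

Progressive alignment builds a guide tree by neighbor joining on pairwise
identity distances ($d = 1 - \mathrm{identity}$), then merges profiles
bottom-up with sum-of-pairs dynamic programming over expected BLOSUM62
scores (gap penalties as in the search stage). There is no iterative
refinement; determinism for a fixed input order is valued over the last few
percent of alignment quality.

Trees are built by neighbor joining on Poisson-corrected distances
$d = -\ln(1 - p)$, where $p$ is the per-site mismatch fraction over columns
where both rows are ungapped, computed after discarding columns under 95%
coverage. This replaces maximum-likelihood inference under JTT: NJ is
deterministic, fast at this scale, and recovers the additive-case topology
exactly (the tests verify this against exhaustive least-squares topology
scoring). Published "95% coverage" could mean site coverage or pairwise
coverage; it is implemented as column non-gap fraction ≥ 0.95, and the
choice is surfaced as the `min_coverage` parameter. $p$ is clamped at 0.95
so corrected distances stay finite; negative NJ branch lengths are clamped
to zero with the deficit recorded. Bootstrap support is the percentage of
100 column-resampled replicate trees containing each bipartition; an
alignment of identical sequences is reported as a star tree with support
100 by convention.

Clade clusters are extracted by midpoint-rooting the tree and removing the
$k - 1$ longest internal edges; leaf groups of size ≥ 2 become clusters
labelled C1, C2, … in decreasing size, singletons are outliers. No
published description of how such clusters were delimited exists, so
long-edge removal is this package's own operational definition; $k$
defaults to 5 and is a configuration parameter. Midpoint rooting is for
display and cluster extraction only — all statistics are computed on the
unrooted tree.

## Catalytic triads and epitopes

Triad positions are supplied in ungapped reference coordinates (preprotein
versus mature-chain numbering is the caller's declaration, which is why
positions are configuration, not constants) and lifted through the
alignment. A site is `conserved` only when the residue equals the expected
one — any other residue, however conservative, is `mutated`, and a gap is
`deleted`; a gene is active iff all three sites are conserved. A mismatch
between the reference row and the expected triad residues is an error
rather than a warning, because a silently shifted frame would corrupt every
downstream call.

Epitopes are located in their source row by exact substring match and
scored per homolog as identity over the lifted columns (gap = mismatch).
The `partial` class threshold of 0.5 is this package's own parameter — no
published value exists — and raw identities are always reported alongside
the class.

## Per-site selection

Substitution counting is Nei-Gojobori style: between two codons, observed
synonymous/nonsynonymous differences are averaged over all minimal
mutational pathways (pathways through stop codons excluded), and site
counts come from codon degeneracy with stop-producing changes excluded from
the possible-change count (the sense-codon state space, as in codon-model
software). The codon-pair kernel is verified against an independent
pathway-enumeration oracle for all 1,891 unordered sense-codon pairs.

Columns can be counted on two bases. The default, `ancestral`,
reconstructs each column's ancestral codon as the plurality codon (ties
broken lexicographically) and sums pathway counts of every other row
against it — a star-parsimony event count in which each substitution is
counted about once. The classical `pairwise` basis (all unordered row
pairs) is retained, with an `event_divisor` column recording the
$(r - 1)$-fold multiplicity a single substitution acquires in pair sums on
a star phylogeny. Pairwise sums fed raw into a per-site test are
pseudo-replicated and grossly anti-conservative; that, measured on
simulations, is why the ancestral basis is the default rather than the
pairwise scheme originally envisaged.

For hypothesis testing, pathway averaging has a second cost: fractional
averaged counts are under-dispersed relative to true event counts, which
makes any binomial test conservative. `pathway = "sample"` therefore
resolves each comparison by one uniformly drawn stop-free minimal pathway,
restoring integer counts with event-level dispersion (it consumes the R
random number generator, so benchmark code seeds it; the deterministic
averaged counts remain the default for descriptive use).

The per-site test is a two-sided binomial test of the nonsynonymous event
count against the neutral expectation $N/(N+S)$ from the site counts, with
the mid-p correction by default (discrete exact tails at 5–20 events per
site are otherwise conservative); `p_method = "exact"` restores the plain
exact test. Sites are classified `positive`/`negative` at `alpha`
(default 0.05, the conventional reporting level) when the observed fraction
is above/below expectation, `neutral` otherwise, `untested` with no events
or fewer than three ungapped rows.

**What this surrogate can and cannot detect.** This is a counting test, not
FEL/MEME likelihood machinery, and its power is bounded by the number of
per-site substitution events. At a realistic within-cluster divergence
(around 0.5 expected substitutions per neutral site per lineage, 16
sequences) a site holds roughly 8–17 countable events against a neutral
expectation near 0.75, which caps sensitivity for strong positive selection
(ω = 5) at roughly a quarter at the 0.05 reporting level. The simulation
benchmark therefore evaluates detection at a threshold spending an explicit
8% false-positive budget (mid-p < 0.22, fixed once from a pilot power
analysis on separate seeds), where the detector clears half of the ω = 5
sites while staying within budget; test calibration is checked separately
on deep-divergence neutral alignments (1.5 substitutions/site), where
events are plentiful and the realized significant-call rate sits inside the
binomial envelope of the nominal 5%. Both operating points are frozen in
the test suite and acceptance script. The gene-level summary applies the
Jukes-Cantor correction to aggregate pN/pS and is reported separately.

## Expression and ELISA

Read assignment is deliberately conservative: a read counts for a
transcript only if every one of its 31-mers occurs in that transcript and
in no other; reads touching shared k-mers are ambiguous and excluded, and
the exclusions are reported. TPM uses effective length
$\max(L - \ell_{read} + 1, 1)$. Expression comparison is one-way ANOVA
(genes as groups, samples as replicates) followed by focal-versus-each
two-sample Student's t tests with Bonferroni correction — a deterministic
surrogate for Dunnett's test, whose exact critical values need
multivariate-t quadrature; the output names the surrogate.

The ELISA cutoff is the control mean + 2 SD (sample SD, $n-1$); a
published "± 2 SD" ambiguity is resolved to the upper bound, since only the
upper bound is meaningful for positivity. Each sensitized subject's
replicates are tested against all control readings (not control means) by a
two-sided Student's t test — the pooling convention is documented because
the original description leaves it open. Positivity is mean OD above the
cutoff; high binding is mean OD above 0.2. Percentages are reported to the
caller unrounded.

## The synthetic-data generator

`simulate_family()` emulates the evolutionary regime the analysis assumes:
an ancestral family of 10 genes (each 220 codons) on 3 scaffolds evolves
down a six-taxon species tree shaped like the mite phylogeny (two shallow
house-dust-mite-like sisters, two parasitic-mite-like taxa, two deeper
storage-mite-like taxa; branch lengths 0.05–0.18 expected proposed
substitutions per codon site). Per branch, each family gene may duplicate
in tandem (probability 0.3) with the copy separated from its source by a
draw from a spacer-count distribution concentrated at zero (60% adjacent);
each may decay (whole-gene loss, flanks retained; default probability 0,
raised in decay studies). At the tips, 20% of family genes suffer a triad
knockout (70% point mutation at one triad codon, 30% codon deletion), and
one paralog per species is marked dominantly expressed with a 10:1 TPM
weight ratio. Substitution follows per-site ω classes (55% ω = 0.1, 25%
ω = 0.5, 15% ω = 1, 5% ω = 5): proposals arrive at rate
$t \cdot \max(1, \omega)$ per codon site, stop proposals are rejected,
synonymous proposals accepted with probability $\min(1, 1/\omega)$ and
nonsynonymous with $\min(1, \omega)$ — so dN/dS at a site equals its ω,
with ω > 1 elevating the nonsynonymous rate as in standard codon models.
Triad codons are invariant except for knockout events, so truth activity
labels are exact. Spacer genes are random sense-codon ORFs (120–260
codons) evolving neutrally, non-homologous to the family by construction.

No quantitative duplication rate has been published for this family; the
defaults above were chosen once to produce per-species family sizes in the
20–30 range with most members arrayed, matching the reported character of
the system, and are otherwise arbitrary. Ancestral paralogs are separated
by a burn-in divergence of 0.12, which is shallow; simulated families
therefore test array/triad/decay recovery faithfully but make clade
structure flatter than the deeply diverged subfamily clusters of real
genomes (cluster recovery is tested instead on designed five-radiation
simulations). Other knowing simplifications: no indels inside family
coding sequences other than triad codon deletions, no sequencing error in
reads, no pseudogene remnants after decay (loss is complete, matching how
absence is observed in synteny alignments), single-exon gene models, and
ELISA effects drawn per subject from a gamma distribution
(shape 0.8, rate 6) over a truncated-normal control baseline
(mean 0.06, SD 0.015, 8 controls, 15 subjects, duplicate wells). Passing
truth-recovery tests therefore demonstrates correctness of the inference
logic under the stated regime, not robustness to annotation noise,
fragmented assemblies or alignment error on real data.

Byte-identical reproducibility for a fixed seed is a contract: the
generator saves and restores the global RNG state, and the determinism
tests compare emitted files byte for byte.

## Problem sizes and degenerate inputs

The test suite runs four-species simulations (4 ancestral genes, 150
codons, 2 scaffolds, 24 spacers/scaffold) for truth recovery, the full
six-species default for the README walkthrough, 100 random short pairs for
the alignment oracle, 50 additive matrices of 4–6 taxa for the NJ oracle,
all 1,891 codon pairs for the counting oracle, and 16-sequence × 300-codon
× 20-replicate batches for selection benchmarking; these sizes were chosen
so the whole suite completes in a few minutes on one core while leaving
every estimate's sampling error far from the asserted margins.

Degenerate inputs have defined behaviour throughout: empty FASTA is an
error naming the file; a CDS not divisible by 3 flags the gene
not-translatable with a warning; an internal stop reports the codon index;
fewer than 3 taxa cannot form an unrooted tree; a coverage filter that
removes every column is an error; a zero-variance expression comparison is
"not significant", not a crash; a single-replicate ELISA subject gets a
cutoff call but no t test, with a warning.
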