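---
title: "Detecting and dating phage-tail-derived gene clusters: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating phage-tail-derived gene clusters: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pltscan)
```

This vignette is the package's own account of its methods: the models and
rules it implements, the parameters that matter and why they default to
what they do, what the synthetic-data generator does and does not
emulate, and the numerical choices that make every run reproducible.

## The object of study

PLTS (phage-like protein-translocation structure) clusters are compact
loci of 13–16 genes derived from contractile phage tails: a baseplate
subcluster (a LysM peptidoglycan-binding protein, the VgrG hub/spike,
a PAAR-repeat spike tip, gp25, Baseplate J, P2-I), one to two copies of
the gp19 tail tube, one to three sheath genes, a gp3-like (DUF4255)
protein and a chaperone-type AAA+ ATPase, the last two typically
head-to-tail. The baseplate gene order is strongly conserved; copy
numbers and the split of VgrG into separate GPD and baseV ORFs vary by
lineage. `plts_profile()` encodes exactly this consensus: family list
with copy ranges, the baseplate order, and the 13–16 size range.

## Detection model

### Homology scan

Every gene is aligned locally (Smith–Waterman, affine gaps) against each
seed protein of each family. We deliberately do not emulate database
E-values: significance depends on database size and is not reproducible
at desk scale. Retention instead uses three deterministic thresholds:

* `min_score_per_length = 0.5` — raw score divided by the shorter
  sequence length. Scale-free across family sizes.
* `min_identity = 0.25` — identity over the local alignment.
* `min_raw_score = 80` — an absolute floor. Length-normalized scores
  over-call *short* seeds on random sequence (a ~100-residue PAAR seed
  needs only a raw score of ~50 to clear the normalized threshold, and
  the null local-score tail reaches that); the floor plays the role of a
  bit-score cutoff. True family members at even 45% identity score
  several-fold above it.

These defaults were calibrated against an empirical null — batches of
i.i.d. random 300-residue proteins drawn from background amino-acid
frequencies — so that a 50-gene random genome yields no hit in ≥ 99% of
replicates, while planted homologs at ≥ 50% identity are always
recovered. Gap penalties are the classical protein-search defaults
(BLOSUM62, open 11, extend 1; a gap of length L costs `open + ext·L`).
`X` is scored 0 against everything: ambiguity is neutral, never
rewarded.

A hit is only *confirmed* if its best reverse hit in the seed genome
lands inside the seed cluster locus and carries the same family. The
seed genome may contain more than one genuine PLTS locus (as real seed
organisms do); any of them counts. Each gene then takes the family of
its best confirmed hit, ties broken by identity and then alphabetically
— documented and deterministic.

### Cluster rules

Confirmed genes are grouped into runs allowing at most 3 intervening
unassigned genes *and* at most 5 kb between consecutive assigned genes
(both configurable); runs never span contigs. Clusters with at least
**ten** core genes are retained — the threshold counts genes, so paralog
copies count individually; a distinct-families mode is available but off
by default. Retained clusters are extended: every gene whose near edge
lies within **4 kb** of the cluster boundary (inclusive — "within 4 kb"
admits a gene at exactly 4 kb) is tested by reverse search against the
seed genome, confirmed genes are merged, and the window is re-examined
from the new boundary until a fixpoint. Iteration matters: a conserved
gene 3 kb out can pull in a second one that was 7 kb from the original
boundary.

### Synteny and architecture

The synteny score is the length of the longest common subsequence
between the cluster's observed baseplate-family order and the consensus
order, divided by 6. The observed order is read 5′→3′ on the cluster's
majority strand, so a cluster written on the minus strand scores
identically to its flipped twin. Architecture typing (sheath/tube/
Baseplate J copy counts, PAAR presence, split VgrG, the ATPase–gp3-like
tandem) is purely positional and needs no alignment.

## Phylogeny

The five markers Sheath, gp25, Baseplate J, LysM and VgrG are aligned
per family by a progressive aligner: pairwise fractional-shared-3-mer
distances, a neighbor-joining guide tree, and profile–profile global
Needleman–Wunsch (BLOSUM62, open 10, extend 0.5) merged in guide-tree
join order. This is a Clustal-type design, not a Clustal-W clone; no
output equivalence with any particular program is claimed, and the
pairwise case provably attains the global optimum (tested against an
independent implementation). Multi-copy families contribute their single
best-scoring copy per taxon.

Concatenation keeps the taxa shared by all families by default
(`gap_fill` keeps the union with all-gap blocks). Distances are
Poisson-corrected, *d* = −ln(1 − *p*), assuming uniform rates across
sites; *p* ≥ 1 is flagged undefined rather than thrown, and undefined
entries must be resolved (error by default, or greedy taxon dropping)
before tree building. Complete gap deletion is the default (columns
gapped in *any* row are excluded globally), pairwise deletion a flag.

Neighbor joining follows Saitou–Nei with the Studier–Keppler Q-criterion.
Numerical choices, all in the service of reproducibility:

* Q-ties are broken by the smallest (i, j) pair in the current taxon
  ordering; the ordering is input order.
* Negative branch-length estimates are clamped to zero; the count of
  clamped branches is kept on the tree
  (`attr(tree, "nj_negative_branches")`).
* The last three lineages join at one node, so the output is genuinely
  unrooted.
* Branch lengths print with `%.10g`, making Newick output byte-stable.

Bootstrap supports come from 1,000 column resamples over the full
supermatrix width; each replicate is distances + NJ, and an internal
edge's support is the fraction of replicate trees containing its
bipartition. Replicates with undefined distances are dropped and
counted, with a warning above 5%. Identical `(input, seed)` gives
identical supports.

## Incongruence and transfer candidates

The cluster phylogeny is compared with a species tree (any Newick input;
the same NJ machinery can rebuild one from a user-supplied supermatrix).
Taxa may be renamed through an injective map first — the usual situation
where a strain is represented by a congeneric proxy in the reference
phylogeny. After pruning to shared taxa, incongruence is the
Robinson–Foulds distance (symmetric difference of non-trivial
bipartition sets), normalized by 2(n−3). Multifurcations are compared by
their bipartition sets directly; the binary-tree normalization is then
conservative. The transfer statistic is leave-one-out displacement:
`rf_reduction(x) = rf − rf after pruning x from both trees`, ranked
descending with alphabetical tie-breaks. The output is a *candidate*
ranking — visual tree comparison, which this statistic formalizes,
cannot by itself distinguish transfer from other sources of conflict,
and neither can RF. Statistical tests of incongruence and
reconciliation-based inference are out of scope.

## The synthetic-data generator

The generator produces every input with known ground truth, under one
master seed that determines every output byte.

* **Species trees** follow a Yule process (two lineages at time zero,
  exponential waits, uniform splitting, one final interval), rescaled to
  a mean root-to-tip depth of `divergence_scale` expected
  substitutions/site. The default 0.3 keeps the most divergent planted
  orthologs near 50–60% identity to the seeds — deep enough to exercise
  the thresholds, shallow enough that a scanner with perfect recall is
  the right expectation.
* **Sequences** evolve in one of two modes with disjoint guarantees.
  `eventwise` draws Poisson(d·L) substitution events per branch —
  realistic multi-branch evolution for topology tests. `bernoulli_pairstar`
  (star trees only) makes each site differ from the root with
  probability 1 − e^(−d) — the exact generative model of the
  Poisson-corrected estimator, used for estimator-recovery tests. No
  single simple simulator provides both exact −ln(1−p) recovery and
  additivity, hence two modes.
* **Transfers** prune the recipient and regraft it onto the donor's
  terminal edge at a seeded uniform position, with the pendant length
  chosen so the tree stays positively weighted.
* **Genomes** carry one planted cluster in consensus layout (copy
  numbers drawn within the profile ranges, rejected until the total is
  in the consensus size range), 50–500 bp seeded spacers, a random
  whole-cluster strand, decoy genes drawn i.i.d. from BLOSUM62
  background frequencies, optionally one conserved flanking gene at a
  configured distance (reverse-confirmable but absent from the seed
  set — the probe for the extension rule), and optionally a partial
  cluster (≤ 9 core genes) on a second contig. Paralog copies are 8%
  perturbations of the family sequence. DNA is reverse-translated with
  uniform synonymous codons purely so GenBank/GFF3 records are
  self-consistent.

What the generator does **not** emulate: indel evolution (alignment gap
handling is exercised on hand-built gapped fixtures instead),
composition biases and low-complexity sequence, operon structure beyond
the cluster, pyocin/T6SS outgroup loci, and rate heterogeneity across
sites. Passing tests therefore demonstrate correctness of the rules and
estimators under the stated model — not robustness to every property of
real genomes; on real data the known failure modes are diverged-past-
detection family members (recall) and compositionally biased proteins
(null calibration).

## Problem sizes and fixed study conditions

The validation suite uses: 20 genomes × (one full cluster, one 9-core
partial cluster, 100 decoys) for the detection contract; a planted
core-count sweep 5..16 for the retention threshold; a 1–8 kb flank
placement sweep (generator seed 7) for the extension window; 100 random
additive matrices of 5–12 taxa for NJ consistency; 100 replicate
10,000-site pairs at d ∈ {0.1, 0.3, 0.7} for estimator recovery; 1,000
bootstrap replicates on a 6-taxon five-marker supermatrix; 100 random
10-leaf tree pairs against an independent RF implementation; and 50
seeded single-transfer simulations on 8–12 taxa for the displacement
ranking. These sizes are the package's chosen study conditions; all are
driven by fixed seeds and rerun identically.

## Known limitations

* The scan is protein-level only; nucleotide-level passes and
  HMM/profile searches are out of scope, as is Pfam-style domain calling
  (domain identities live as family labels on seeds).
* E-value statistics are intentionally absent; thresholds are calibrated
  on the package's own null, not comparable to BLAST E-values.
* NJ with Poisson correction saturates for p → 1; deeply diverged
  marker sets need upstream taxon dropping.
* Rooting is never inferred; all comparisons are on unrooted topologies.
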