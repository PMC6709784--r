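---
title: "Methods: building and characterizing a pan-NLRome"
author: "pannlrome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and characterizing a pan-NLRome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind the package, in the order the pipeline runs them. The
package analyzes the *pan-NLRome* of a species: the union, across a
panel of accessions, of nucleotide-binding leucine-rich-repeat (NLR)
immune receptor genes, their domain architectures, orthology structure
and allelic diversity.

## Domain classification

Input is a table of per-gene protein-domain intervals (1-based,
inclusive, protein coordinates) from Pfam-style predictors plus three
coiled-coil tracks (`coils`, `paircoil`, `nlrparser`). Pfam accessions
of the canonical domains are mapped to tokens first; all four LRR-family
models collapse onto a single `LRR` token, so downstream logic never
sees raw accessions.

*NLR identification* requires at least one NB, TIR or RPW8 domain; LRR
or CC hits alone are insufficient (they are common outside NLRs).
*Coiled-coil consensus* is residue-wise two-of-three voting: a residue
counts as coiled-coil when intervals from at least two distinct
predictors cover it, and maximal supported runs become consensus
intervals. Voting residue-wise (rather than interval-overlap pairwise)
makes the consensus monotone in added evidence, a property the test
suite checks.

*Classes* are assigned with the precedence TIR → TNL, else RPW8 → RNL,
else CC together with NB → CNL, else NB → NL. The four textual class
definitions overlap (a gene may carry both TIR and CC); the precedence
turns them into a partition, following the field's naming convention in
which the TIR and RPW8 N-termini dominate. *Architectures* are collapsed
domain sets — duplicate and repeated domains are not distinguished and
order is dropped — while the ordered domain string is retained as
metadata, since cartoons of ID-containing genes are conventionally drawn
ordered. Non-canonical domains inside NLRs are integrated domains (IDs);
IDs seen in exactly one gene model of exactly one accession are flagged
singletons and excluded from novelty counts, to limit the impact of
annotation artifacts.

## Orthogroup construction

All-against-all full-length protein similarity uses exact local
(Smith-Waterman) alignment with BLOSUM62 and affine gaps, gap open 11 /
extend 1, with a gap of length $L$ costing $11 + L$ (the BLAST
convention). At desk scale (thousands of genes) exact alignment is
affordable, so no heuristic search engine is needed; a k-mer prefilter
(pairs sharing ≥ 3 distinct 4-mers) skips pairs with no seed similarity
— unrelated proteins essentially never pass it, while family members
share many k-mers. Scores below 50 are dropped (a lenient homology
floor), and scores are also normalized to $[0,1]$ by the smaller
self-score.

Edges are typed with reciprocal-best logic: a between-accession edge is
an *ortholog* iff each end is the other's best hit in that accession
(ties retained as co-best — the tie-breaking of the original tool is
undocumented, so both edges are kept); a within-accession edge is an
*inparalog* iff its score is at least both members' best
between-accession scores; *co-ortholog* edges connect inparalogs of
reciprocal-best partners. Untyped edges are excluded, so only
orthology-consistent similarity reaches clustering.

Markov clustering runs on the typed-edge graph with the normalized
scores as weights, inflation 1.5 and minimum cluster size 2. Numerical
choices the method leaves open: self-loops are set to the maximal
incident edge weight (standard MCL practice), entries below $10^{-5}$
are pruned each iteration, convergence is a maximum entry change below
$10^{-6}$, and the iteration cap is 100 (non-convergence returns the
current interpretation with a warning — in practice the block-structured
graphs here converge in well under 50 iterations). Clusters are read off
as connected components of the converged attractor matrix, which makes
the result independent of input ordering.

## Orthogroup refinement

Orthogroups with more than 4 members are screened for outliers and
paralogs. The progressive aligner builds a 3-mer distance matrix, a
UPGMA guide tree, and merges alignment blocks by global profile-profile
alignment (BLOSUM62, same gap convention; the dynamic program is the
package's only compiled code). Within-orthogroup sequences are close
homologs, so profile frequencies with gap mass simply dropped are
adequate; for two sequences the result provably attains the brute-force
global optimum, which the tests verify.

Outlier members (non-homologous, mistranslated or low-similarity
sequences) are flagged by their mean pairwise distance: the column set
is bootstrapped (100 replicates) to estimate each row's spread, and rows
whose observed mean exceeds the 20%-trimmed across-row mean by more than
3 bootstrap standard deviations are removed and logged. Fewer than five
rows is a no-op — with so few members a "distance outlier" is not
meaningful.

Protein alignments are back-translated to codon alignments (residue →
codon, gap → `---`), with trailing stop codons excluded and any
CDS/protein disagreement reported as an error naming the gene and the
first mismatched residue. Trees are neighbor-joining on p-distances with
pairwise gap deletion (the distance model of the original tool is
unstated; p-distance is the simplest choice consistent with the low
within-orthogroup divergence), negative NJ branch lengths clamped to
zero, and 100 codon-column bootstrap replicates giving percent supports.

Duplication detection midpoint-roots the tree first (the original
splitting tool does not state its rooting; midpoint is the conventional
choice without outgroups, with a fallback to rooting at the first leaf
when the tree has zero total length). A node is a duplication when some
accession occurs in more than one child clade; it is *simple* when the
two occurrences are sister leaves and *complex* otherwise. The **5%
rule** then decides between pruning and splitting: with $f$ = (accessions
with within-orthogroup duplicates) / (occupied accessions), $f \le 0.05$
prunes all paralogs — keeping, per duplicated accession, the member with
the smallest root-to-leaf path, i.e. the most conserved copy, a survivor
criterion the original description leaves open — while $f > 0.05$ splits
the tree at its duplication nodes, promoting every resulting leaf set of
≥ 2 to a new orthogroup and demoting the rest to singletons. Whether
"accessions with duplications" should count only simple duplications is
ambiguous; the package counts any duplication.

Refined orthogroups are typed by size — cloud < 13, shell 13–51, core
> 51 members — and annotated by majority votes (class, clustered flag;
a class tie resolves to the lexically first label with a warning), an
any-member vote for the ID flag, and total tree length divided by
orthogroup size.

## Physical organization

Physical NLR clusters chain genes on the same contig whose
start-to-start distance is within 200 kb, by single linkage (the 200-kb
rule's chaining is unspecified in its source; single linkage is the
permissive reading, so a 0 / 150 kb / 300 kb chain is one cluster), and
only chains of ≥ 2 genes count. Head-to-head pairs are adjacent genes,
left on the minus and right on the plus strand, with 5′ ends at most
10 kb apart — the source gives no bound, but its control pairs sit
< 4 kb apart, so 10 kb is permissive yet bounded.

## Diversity and neutrality statistics

Statistics are computed per codon alignment on the gap-filtered column
set. Default gap handling is *complete deletion* (every column with a
gap in any row is excluded); a pairwise-deletion mode is provided for π.
With $n$ rows, $L$ retained sites, $S$ segregating sites, $\eta$
mutations, $\eta_s$ singleton mutations and $k$ the mean pairwise
difference count: π = $k/L$, $\theta_W = S/(a_1 L)$ with
$a_1 = \sum_{i<n} 1/i$, haplotype diversity $= n(1-\sum p_i^2)/(n-1)$,
Tajima's D with the standard variance constants, Fu & Li's D\* and F\*
in the star (no outgroup) variants with the corrected variance
polynomials — no outgroup exists per orthogroup, so the starred forms
are the only applicable ones — R2 from per-sequence singleton counts,
and Strobeck's S as the Ewens-sampling probability of at most the
observed number of haplotypes at $\hat\theta = S/a_1$ per locus,
computed with a log-space unsigned-Stirling-number recursion (stable to
large $n$). Undefined statistics (D with $S=0$; D\*/F\* for $n<4$) are
`NA`, never zero; Strobeck's S is 1 when $\hat\theta = 0$.

Per-domain statistics annotate each alignment codon column by a
plurality vote of its non-gap residues' domain labels (unannotated
residues vote `none`; ties resolve to `none`) and run the same
statistics on the concatenated columns of one domain. Invariable codons
require all rows non-gapped and identical — a gap anywhere disqualifies
the codon, since a gapped column cannot attest invariance.

Flag enrichment is an upper-tail hypergeometric test per orthogroup ×
flag with Benjamini-Hochberg correction across all combinations and a
q < 0.1 reporting threshold. The expression threshold subtracts the
kernel density of intronic background counts from that of NLR counts on
a shared log10(count+1) grid and takes the lowest level with a positive
excess; identical distributions yield a sentinel `NA`.

## Saturation, anchoring, quality

Rarefaction draws accession subsets without replacement — each
replicate permutes the panel once and uses its k-prefixes, which are
exactly uniform k-subsets at every size — 1000 replicates for
orthogroup discovery (sizes 2..N, with percentile intervals and the
mean membership of still-undiscovered orthogroups) and 100 for the
fraction of nucleotide and haplotype diversity recovered. Sampling with
replacement was rejected: the question is how many *distinct*
accessions are needed.

Co-occurrence networks connect orthogroups found on the same contig,
with edge weight = number of supporting accessions (counted once per
accession even with several shared contigs, so multi-contig accessions
cannot inflate support). Edges below 10 accessions are dropped;
components of ≥ 2 nodes are subnetworks; each orthogroup without a
reference allele takes the reference interval of its highest-weight
anchored direct neighbor (ties → smallest genomic coordinate). This
replaces the manual inspection used in the original workflow with an
automated, documented proxy; orthogroups whose component has no
anchored neighbor stay unanchored.

Assembly quality is $Q = |-10\log_{10}(\mathrm{hetsites}/
\mathrm{totalsites})|$ (the absolute value is kept verbatim although
the ratio ≤ 1 already makes the expression non-negative), with zero
hetsites reported as `Inf`. Completeness estimates interpolate a
monotone (Q, completeness) calibration table piecewise-linearly, clamped
at the calibrated range — extrapolating beyond assemblies ever measured
would be invention. The calibration table and the het-site counts are
inputs: producing them requires read mapping and assembly, which is out
of scope; a synthetic sigmoid calibration fixture is generated in code
and labelled synthetic.

## The synthetic pan-NLRome simulator

The simulator is first-class, tested code; it generates the study
conditions for everything above. Per orthogroup it draws presence per
accession as independent Bernoulli trials from a spectrum; member coding
sequences descend from a random stop-free ancestral CDS along a Kingman
coalescent genealogy (exponential waiting times, time in units of 2N)
with Poisson(θ/2 · branch · sites) Jukes-Cantor mutations — the simplest
neutral model matching the statistics tested downstream, with the
property that two sequences differ at rate θ per site in expectation.
Mutations that would create an in-frame stop are discarded so every CDS
stays translatable. Gene conversion copies exponential-length tracts
between members; a configurable fraction of orthogroups carries one
within-accession duplicate copy diverged by an additional 2θ, enabling
the 5% rule to be tested against known truth.

Domain architectures follow class templates (two LRR intervals to
exercise collapsing; CC emitted as overlapping predictor tracks so the
two-of-three vote must recover it); a configurable fraction of genes
(default 0.05) appends an integrated domain from a fixed catalogue of
10 arbitrary labels — the labels carry no meaning, the structure does.
Genes are laid out on contigs: paired orthogroups adjacent and
divergently transcribed 1–8 kb apart, physical clusters of 2–4
orthogroups with uniform 2–50 kb spacing (one contig per cluster plus
singleton contigs, mimicking enrichment-assembly fragmentation), random
strands elsewhere, and rare annotation flags on 2% of genes.

Defaults (chosen once as the package's study conditions): 64 accessions;
spectrum 35 orthogroups at presence 0.95, 45 at 0.5, 70 at 0.12 — 150
orthogroups whose core/shell/cloud proportions echo a real species-wide
NLR panel; per-site θ = 0.02 (within-orthogroup nucleotide identity
≈ 98%, far above the ≥ 80% regime in which clustering must succeed,
while independent random ancestors keep between-orthogroup protein
identity below any homology floor); protein lengths 80–120 codons —
short for real NLRs (≈ 1000 aa) but preserving every structural feature
at desk scale; class mix TNL/CNL/RNL/NL = 0.58/0.22/0.07/0.13, the
reported proportions for a Brassicaceae panel; 10% paralog-seeded
orthogroups; 10% paired; conversion rate 0.05 events/gene with 120-bp
mean tracts.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: annotation error (all gene models are
correct), indels and alternative splice forms (alignments of truth
members are gap-free, so column filtering is exercised only after
refinement removes members), sequencing/assembly artifacts, selection
(all diversity is neutral), population structure (accessions are
exchangeable), and realistic domain-prediction noise (intervals are
exact, so architecture recovery is expected to be perfect).

## Problem sizes and runtime

The shipped tests run reduced configurations (8–16 accessions, 14–28
orthogroups) for module checks, and the acceptance suite runs the full
default conditions (64 accessions, 150 orthogroups, ≈ 4000 genes) once
for clustering-plus-refinement truth recovery; the end-to-end acceptance
script completes in a few minutes on one CPU. Monte-Carlo checks use
200–1000 replicates with three-standard-error bands.

## Known limitations

Tree inference is distance-based (NJ) with bootstrap supports; no
likelihood or Bayesian refinement. The aligner is progressive without
iterative refinement. Edge typing retains co-best ties rather than
resolving them. Anchoring uses direct anchored neighbors only. The
coordinate convention is 1-based inclusive end to end (the GFF3/GRanges
convention native to this ecosystem), with explicit converters to
0-based half-open at interchange boundaries.
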