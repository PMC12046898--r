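---
title: "Methods: synteny, ancestral karyotypes, molecular dating and multi-omics networks"
author: "palmkaryo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synteny, ancestral karyotypes, molecular dating and multi-omics networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

palmkaryo re-implements, as tested code, the comparative-genomics and
multi-omics analyses used to interpret a haplotype-resolved palm genome:
collinear synteny-block detection, ancestral-karyotype reconstruction with
whole-genome-duplication (WGD), fusion and fission accounting, synonymous
(Ks) and LTR-based molecular dating, allele-specific-expression (ASE)
calling, and gene–metabolite correlation networks. Every stage can be
exercised end-to-end on a built-in simulator with known ground truth, so the
statistical behaviour of each estimator is measurable rather than asserted.

This vignette documents the models, their assumptions, the tunable
parameters, the numerical choices, and what the simulator does and does not
emulate.

# The genome simulator

`make_ancestor()` lays out an ancestor of `n_chrom` chromosomes with
`genes_per_chrom` ordered, non-overlapping genes (internal coordinates are
0-based half-open; GFF3 output is 1-based inclusive). Evolution proceeds by
events: `wgd_event()` (and `wgt_event()` for triplication) duplicates every
chromosome and extends each gene's copy label; `fusion_event()` concatenates
two chromosomes, optionally reversing the second; `fission_event()` splits
at a gene-rank breakpoint; `inversion_event()` reverses a rank interval and
flips strands; `loss_event()` models fractionation by dropping gene copies
independently at `1 - retention`. Two guards keep the ground truth usable:
an ancestral gene never loses its last copy (homology stays connected), and
a chromosome never loses its last gene (the chromosome-count algebra
`n -> 2n` per WGD, `+1` per fission, `-1` per fusion stays exact, which is
property-tested against `event_accounting()` on random scenarios).

The canonical study system is a six-chromosome ancestor evolved through two
lineages. `palm_scenario()` encodes the palm-like history — first WGD
(n = 12), two fissions and five fusions (n = 9), second WGD (n = 18), one
fission and three fusions (n = 16) — with a fractionation epoch (default
retention 0.8) after each WGD. `waterweed_scenario()` is the companion
lineage ending at n = 20; its event list is a free parameter of the
simulator, not an inference about any real species. Two deliberate choices:
fission breakpoints sit mid-chromosome so fission products stay detectable,
and no unordered pair of ancestral chromosomes is fused by more than one
event across the two lineages. The second choice matters: a junction
between the same two groups created independently two or three times is, to
any parsimony method, indistinguishable from ancestral adjacency (it becomes
a majority signal), so a simulator that reused fusion pairs would make its
own truth unrecoverable in principle.

What the simulator does not emulate: sequence-level rearrangement
breakpoints, tandem duplications, gene movement without rearrangement,
read-level noise, and lineage-specific gene family expansion. Tests passing
on this simulator show that the algorithms recover the planted signals under
clean rank-space collinearity; on real annotations, tandem arrays and
annotation noise will loosen block purity.

## Sequence-pair simulators

`simulate_codon_pair()` diverges a random coding sequence to a target
synonymous divergence: the number of accepted synonymous substitutions is
Poisson with mean `ks_target` times the Nei–Gojobori synonymous site count,
and the realized truth is the accepted event count over those sites. By
default codons are drawn from the fully fourfold-degenerate families
(GCN, GTN, GGN, CCN, ACN, TCN). On these codons every synonymous change is a
third-position change with three equally likely alternatives, so synonymous
evolution is exactly a Jukes–Cantor chain and the target is identifiable.
With `alphabet = "all"` (all sense codons) twofold-degenerate sites behave
as two-state chains that saturate faster than the Jukes–Cantor model
assumes, and any JC-corrected estimator is upward-biased at high Ks (about
+0.18 at Ks 0.9 in our measurements); the option exists precisely so that
this bias can be demonstrated. Hit counts per codon are drawn multinomially
(uniform over codons), which matches the accepted-event distribution of the
underlying proposal process on fourfold codons.

`simulate_ltr_element()` applies independent substitution streams at rate
`mu` for `age_T` years to two initially identical LTRs; the realized
divergence is the logged event count over the length, with expectation
`2 * mu * age_T`.

## Expression and metabolome simulators

`simulate_expression()` gives each allelic pair a gamma baseline and a
shared log-normal tissue modulation; counts are log-normal multiplicative
noise around the mean, one library per (tissue, replicate, haplotype), with
the other haplotype's rows zero — the layout produced by quantifying each
library against each haplotype separately. A planted fraction of pairs
carries a true allele fold change, alternating direction between
haplotypes. Distributional fidelity to a negative-binomial count model is
not attempted: the ASE criteria act on TPM means and a replicate-level
test, so the log-normal model exercises them fully.

`simulate_metabolome()` makes a planted fraction of metabolites linear
functions of a partner gene on the log2 scale, with the noise residualised
against the partner so the planted in-sample correlation equals `target_r`
exactly; unlinked metabolites are independent log-normal noise. Partners
are preferably drawn from genes whose in-sample correlation with every
other gene stays below an identifiability bound (default 0.6). The reason
is statistical, not cosmetic: with nine samples the null standard deviation
of a correlation coefficient is about 0.35, and a planted link to a gene
that is itself strongly correlated with other genes cannot be distinguished
from links to those genes at any |r| threshold. A planted "truth" is only
a truth when the partner is identifiable; outside that regime the generator
warns and precision against planted labels loses its meaning (the analysis
scripts print such a case deliberately).

# Synteny blocks

`build_anchors()` turns homolog pairs into rank-space anchors (dense gene
ordinals per chromosome, sorted by start). Homology search itself
(BLAST/DIAMOND-style) is out of scope; the module consumes a pair table,
which in the simulated analyses is the ground-truth homology.

`chain_anchors()` extracts collinear chains per chromosome pair: both ranks
strictly increase along a `+` chain (rank_b strictly decreases along `-`),
consecutive rank gaps are bounded by `max_gap` (default 25) in both genomes,
the score is the anchor count, and chains below `min_block_anchors`
(default 5) are discarded — MCScanX-like defaults. Multi-hits sharing a
rank are collapsed to the partner with the smallest rank first, which
prevents degenerate vertical or horizontal chains.

Extraction solves a disjoint chain-packing problem. Chromosome pairs with
at most `exact_limit` (default 12) anchors are solved to optimality by
exhaustive chain enumeration plus branch-and-bound packing (the incumbent
bound makes clean diagonals essentially free); larger pairs use best-first
greedy extraction with used anchors removed. Pure greedy is provably
suboptimal on small instances — with a minimum block size of 2, any two
leftover anchors of a permutation still form a chain, so the optimum covers
every anchor while greedy can strand one by parity — which is why the small
instances, the ones a brute-force oracle can check, are solved exactly.
The test suite compares extraction against an independent
subset-enumeration oracle on 1000 random instances.

`block_multiplicity()` slides non-overlapping windows of gene ranks
(default 20) along each genome and counts distinct blocks covering each
window; the modal count over covered windows is the genome's syntenic
multiplicity. Two WGD rounds per lineage give the expected 4:4 profile. A
property worth knowing: because ranks recompact after gene loss, unbiased
fractionation does not reduce window multiplicity (verified down to
retention 0.1); multiplicity falls only when whole duplicate copies are
lost.

`find_allelic_pairs()` claims anchors best-block-first so each gene enters
at most one pair, aligns the paired CDS globally (Needleman–Wunsch, match
+1, mismatch -1, gap -2), and classifies identity as `identical` (100%),
`similar` (at or above `similar_threshold`, default 80%) or `diverged`.
The 80% boundary is a package default; the source data only distinguish
identical from non-identical.

# Ancestral karyotype reconstruction

`infer_ancestral_groups()` formalises the manual "colour the dotplot"
reading. Block sides are split at the union of all block boundaries on each
chromosome (a common segmentation into atomic intervals), and every chained
anchor joins the atomic interval of its gene to that of its partner.
Connected components of this anchor graph gather segments descending from
one ancestral chromosome. Whole-segment overlap rules were tried first and
fail structurally on two-WGD histories: after a fusion and a later WGD, the
two sibling chromosomes are collinear across the fusion junction, so a
self-synteny block spans two ancestral groups and any overlap-based edge
fuses them into one component. Cutting at the common segmentation removes
exactly that failure, because cross-genome blocks (whose partner lineage
does not share the fusion) end at the junction.

Lineage-specific fissions leave the opposite failure: an ancestral
chromosome split in one lineage yields two components. A
majority-adjacency merge repairs this: two components are joined when their
atoms are immediate neighbours on more than half of the chromosome copies
carrying them (counted at most once per chromosome). Ancestral continuity
broken by one lineage's fission remains adjacent in most copies; a fusion
junction is adjacent only in the fused copies. Components below
`min_component_genes` (default 30) neither vote nor bridge — small spurious
components near junctions otherwise transitively merge real groups — and
are dropped from the output.

`paint_chromosomes()` assigns genes to groups, merges runs (unassigned
genes do not break a run) and keeps runs of at least `min_segment` genes
(default 10). `infer_event_scenario()` counts junctions between
different-group segments as fusions. With two WGD rounds, a fusion that
happened before the last WGD leaves two copies of its junction (same group
pair, similar flank sizes, matched within `size_tol`, default 0.3); paired
junctions count once as early fusions. Fission totals then follow from the
chromosome-count algebra `n_final = 4 n0 + 2 (fi1 - fu1) + fi2 - fu2`,
placing fissions as early as possible (early events move the final count
twice as far, so this is the minimal-event solution). Per-epoch placement
beyond that is not identifiable from a single painting and is reported as
such. On the canonical simulation the recovered totals are exactly the
planted (2 fissions, 5 fusions) + (1 fission, 3 fusions).

`project_composition()` transfers group labels across blocks onto a third
genome, resolving overlaps per gene rank by block score; projecting the
reference onto itself is the identity, and a triplicated test lineage shows
each group on three chromosomes.

# Molecular dating

`nei_gojobori_ks()` is the classic pathway-counting estimator: synonymous
site fractions per codon (averaged over the two sequences), differences
averaged over all shortest mutational pathways (pathways through stop
codons excluded; if every pathway is blocked the count falls back to
including them), and Jukes–Cantor correction
`Ks = -3/4 log(1 - 4/3 pS)`. Saturation (`pS >= 3/4`) is an error, not an
NA, for the single-pair interface; the vectorised `ks_table()` converts it
to NA with a warning. Measured on the simulator at 10,000 codons the bias
is below 0.01 across Ks 0.1–0.9.

`detect_ks_peaks()` evaluates a Gaussian kernel density on a fixed grid
(0 to 3, step 0.005; values above 3 discarded as saturation noise) with
Silverman's rule as the default bandwidth, and reports local maxima above
10% of the global maximum. `calibrate_rate()` and `date_event()` implement
the molecular clock `T = Ks / (2 r)`; calibrating the older WGD peak
(Ks 0.9) at 80.34 Mya dates the younger peak (Ks 0.3) at 26.78 Mya.

`k2p_distance()` is the Kimura two-parameter distance (transitions P,
transversions Q, ambiguity codes and gaps excluded pairwise), cross-checked
in the tests against `ape::dist.dna(model = "K80")`. `ltr_insertion_age()`
applies `T = D / (2 mu)`. The default `mu = 5.6e-10` per site per year is
the published value of the source workflow; note that a rate calibrated
from the palm Ks peaks (0.9 / (2 x 80.34 Myr) ~ 5.6e-9) is tenfold higher,
so `mu` is an explicit argument everywhere and reported tables carry it.
The package takes no position on which rate is right.

# Allele-specific expression

`compute_tpm()` is the standard within-sample normalisation; nonzero
columns sum to one million. `call_ase()` tests each allelic pair per
tissue: the larger allele mean TPM must exceed 1 (`tpm_rule` can demand
both alleles or the pair mean instead), |log2 fold change| of the allele
means must exceed 1, and a two-sided Welch t-test on log2(TPM + 1)
replicate values must give p < 0.05 — all strict inequalities, so a fold
change of exactly 2 fails. Zero-variance degeneracies are deterministic:
equal means give p = 1, unequal means p = 0. The replicate-level Welch
choice is the package's own (the source workflow used an unspecified
script); it is symmetric under haplotype swap, which is property-tested.
`classify_specificity()` bins called pairs into one-tissue / multiple /
all-tissues. `screen_degs()` applies the same Welch machinery between
tissues with Benjamini–Hochberg adjustment across genes; it is a
transparent stand-in for a negative-binomial DEG model, with the thresholds
(|log2FC| > 1, adjusted p < 0.05) applied exactly. On planted effects the
caller reaches sensitivity above 0.9 with empirical FDR below 0.1, and the
null call rate stays under the nominal level plus filter slack.

# Metabolite screening and networks

`plsda_vip()` fits PLS2 by NIPALS on autoscaled variables against centred
one-hot group membership and returns
`VIP_j = sqrt(p * sum_a(SSY_a (w_aj/||w_a||)^2) / sum_a SSY_a)`; squared
VIPs average to one by construction (asserted to 1e-6), zero-variance
variables are excluded with a warning, and a Y-unrelated X ends component
extraction cleanly with zero VIPs. Two components and autoscaling are the
defaults; the first NIPALS weight vector is checked against an
eigen-decomposition oracle. `screen_dams()` combines a strict group-mean
fold change (> 2 or < 0.5) with VIP > 1.

`build_correlation_network()` correlates metabolites with genes on
log2(x + 1) (Pearson by default, Spearman by flag), ranks genes per
metabolite by |r|, truncates to the top `top_k` (5) and then filters at
|r| > `r_threshold` (0.8); `rule = "filter_first"` swaps the last two
steps, which matters only when more than five genes pass the threshold. A
metabolite with fewer qualifying genes keeps fewer edges; the threshold is
never relaxed. Edge sign is the correlation sign. Exports to GraphML and
SIF go through igraph. The statistical caveat from the simulator section
carries over: at n = 9 the |r| > 0.8 rule reliably separates planted links
only from an identifiable gene pool, and the replicate-level correlation is
preferred over per-tissue means exactly because three means leave one
effective degree of freedom.

# Telomere scanning

`scan_telomeres()` counts exact occurrences of the plant telomere unit
(TTTAGGG; its reverse complement CCCTAAA at the 5' end) in 10 kb terminal
windows, with half-length windows on short sequences so the two ends never
overlap, and calls an end telomeric at `min_copies` (10) or more. Counting
is exact string matching with no mismatch tolerance — the motif is
configurable but the scan is deliberately a counter, not a repeat-discovery
tool. Reverse-complementing a chromosome swaps the two ends' counts
exactly, which is property-tested.

# Problem sizes and determinism

The shipped analyses and the test suite run on a 1200-gene, six-chromosome
ancestor (about 3100 genes per evolved genome, roughly 8000 cross-genome
anchors), 300–400-codon CDS cohorts with 10,000-codon pairs for bias
measurement, 200–500 allelic pairs across twelve tissues with three
replicates, and 25–50 metabolites over nine samples — sizes chosen so every
stage re-runs from scratch in seconds to a few minutes on one core while
keeping the statistical checks meaningful. All generators are
bit-reproducible under a fixed seed (`withr::with_seed` internally); the
analysis scripts fix seed 20250502.

# Known limitations

* Rank-space collinearity ignores physical distances; bp-resolution block
  boundaries and nucleotide-level alignment are out of scope.
* Group inference assumes the two genomes do not share derived fusion
  junctions; shared (ancestral or convergent) fusions would be painted as
  ancestral adjacency, which is exactly how a human reader of a dotplot
  would also mis-read them.
* Per-epoch placement of fissions is reported under greedy parsimony and is
  not identifiable from a single painting.
* The DEG and DAM screens are transparent replicate-level tests, not count
  or intensity models with shrinkage; with three replicates their power is
  limited and the thresholds dominate.
* The Ks estimator shares the usual Nei–Gojobori assumptions (no
  transition/transversion bias, uniform codon usage); its bias bound is
  measured on the simulator's fourfold-degenerate regime.
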