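---
title: "Methods: ortholog calling, dN/dS selection scans and expression contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ortholog calling, dN/dS selection scans and expression contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`orthoselect` implements the inference chain used in comparative liver
transcriptomics of recently diverged species trios: candidate orthologs are
called by three-way reciprocal best hits, cleaned by a Gaussian-mixture
filter on synonymous divergence and by Markov-cluster concordance, scored
for selection with pairwise dN/dS, and summarised by rank-based GO
enrichment; a parallel expression stage runs negative-binomial
likelihood-ratio tests, pairwise contrasts, Manhattan-distance principal
coordinates and a marker-based outlier-sample screen. Every stage is
driven by a synthetic-data module with known truth, so the package's tests
measure recall and calibration directly rather than re-describing any
particular dataset.

## The study system emulated by the generator

The default generator mimics a trio of sympatric reef fish: two sister
species (labelled HCAR and HMAC) that split roughly 2 Ma and an outgroup
(HFLA) diverging from them roughly 5 Ma, on the fixed topology
`((HCAR, HMAC), HFLA)`. Branch lengths are expressed in expected
synonymous substitutions per synonymous site, with defaults
`internal = 0.03`, `A = B = 0.02`, `C = 0.05`; these give pairwise
synonymous divergence of about 0.04 between the sisters and about 0.10 to
the outgroup, proportional to the divergence times and shallow enough that
protein identity between true orthologs stays comfortably above the 75%
acceptance threshold, as it does in real transcriptomes of species this
young. Gene lengths are uniform on 100-300 codons (the short end of
assembled liver transcripts). The gene pool is 85% purifying
(omega uniform on 0.05-0.4), 10% effectively neutral (0.9-1.1) and 5%
positively selected (1.2-2.5), so a few percent of all pairwise
comparisons have omega above 1, matching the order of magnitude reported
for such trios. Five percent of genes carry a paralog contaminant: one
randomly chosen species' copy is replaced by a duplicate evolved for an
extra 0.4 synonymous units (at least three times the tree depth), the
signature of mistaking an out-paralog for the ortholog.

## The codon-evolution model

Sequences evolve by proposal thinning rather than a full codon rate matrix
(GY94-style). Mutation events arrive as a Poisson process with `mu = 1`
proposal per nucleotide site per unit branch length; each event proposes a
uniform alternative base; proposals creating stop codons are rejected
outright, so every emitted CDS stays in frame and stop-free. Selection
enters only through acceptance: for omega at or below 1, synonymous
proposals are always accepted and nonsynonymous ones with probability
omega; for omega above 1 the roles flip, with synonymous proposals
accepted at rate 1/omega. The expected nonsynonymous/synonymous rate
ratio therefore equals omega *by construction*, which is what makes the
estimator testable: the simulator exports proposal and acceptance
counters, and a test verifies the acceptance rates directly. The
parameterisation has one deliberate asymmetry: a branch of length t yields
expected dS = t when omega is at most 1 but dS = t/omega when omega
exceeds 1 (the synonymous rate is thinned instead). Setups that target a
given realised dS for positively selected genes therefore scale branch
lengths by omega; the estimator-recovery checks do exactly that.

The simulator deliberately omits indels, codon-usage and GC bias,
among-site rate variation, transition/transversion bias and recombination.
Passing tests therefore demonstrate correctness of the estimators under a
clean substitution process, not robustness to alignment error or
compositional confounders in real data.

## Ortholog calling and filtering

Protein similarity is computed with an affine-gap Smith-Waterman
(BLOSUM62, gap open 11, extend 1, a gap of length k costing
`open + k * extend`). Traceback tie-breaks are fixed (diagonal, then up,
then left; first maximum in row-major order starts the traceback), so hit
tables are fully deterministic. Bit scores use the published ungapped
BLOSUM62 Karlin-Altschul constants (lambda 0.267, K 0.041) even though
alignments are gapped: these e-values only rank and gate orthology calls,
so rank fidelity matters and absolute calibration does not. External hit
tables in the standard 12-column tabular dialect can be substituted for
the internal search; downstream results depend only on the hit records.

A hit supports orthology when e-value < 1e-5, identity > 75% and the
alignment covers more than half of the subject protein (the subject's
full length, not the HSP span). A triplet is called when the reference
species' gene (HMAC by default) is a reciprocal best hit with one gene in
each other species *and* those two genes are reciprocal best hits with
each other - the strictest three-way reading. Best-hit ties are broken by
bit score, then e-value, then subject id.

Two independent checks then vote. First, each candidate group is
summarised by its mean pairwise dS and a three-component univariate
Gaussian mixture is fitted to the pooled summaries; every group assigned
by maximum posterior to the highest-mean component is dropped as a
probable paralog. (Fitting three values per group would be meaningless, so
pooling is the only sensible reading.) Second, Markov clustering - the
algorithm family behind OrthoMCL/FastOrtho - is run on the
`-log10(e-value)` similarity graph (weights capped at 200, self-loops at
the node maximum, inflation 1.5) and a group must have all three members
in one cluster. Only groups passing reciprocal best hits, the dS filter
and the cluster check are retained; the retention fraction is reported.

## Pairwise dN/dS

The estimator is Nei-Gojobori (1986) counting with equal pathway weights
and Jukes-Cantor correction. Sites: each of a codon's nine
single-nucleotide mutants is classified synonymous or nonsynonymous
(stop-codon mutants count as nonsynonymous); the synonymous fraction per
position sums to the codon's synonymous sites. Differences: for codon
pairs differing at k positions, Nd and Sd are averaged over the k!
orderings that avoid stop codons; if every pathway is blocked the column
is dropped and counted. Proportions pN and pS are corrected with
d = -3/4 log(1 - 4/3 p); pS at or above 3/4 marks saturation and excludes
the pair from mixture fitting, and dS = 0 leaves omega undefined. Pairwise maximum likelihood under a codon model (codeml-style) is the
heavier alternative; NG86 was chosen here because it is fully specified, exactly testable against
brute-force enumeration, and adequate at the shallow divergences the
generator targets (the estimator-recovery test requires the median
estimate within 20% of truth per omega class at 300 codons). Externally
computed pairwise ML tables can be fed to the downstream filters in place
of the internal estimator.

Genes with omega above 1 are filtered per species comparison (AB, AC,
BC): a four-component mixture is fitted to the omega values above 1 and
the highest-mean component removed as unrealistic - with fewer than four
such values the mixture is skipped for a hard omega < 3 cut, with a
warning. A gene is called positively selected only if 1 < omega < 3 after
the filter; the empirical boundary between the two highest components is
reported alongside.

## Mixture machinery

`fit_gmm()` is a standard univariate EM, converging when the
log-likelihood gain falls below 1e-8 (cap 500 iterations), with free
variances (the more flexible one-dimensional family) kept above 1% of the
data variance - a regularisation against degenerate likelihood spikes -
and above an absolute 1e-8 numerical floor. Components are stored sorted
by mean, so "highest component" always means the last one. Model order,
where searched, is selected by BIC `-2 logL + (3k - 1) log n`, ties to
the smaller k.

Initialisation deserves a note, because it is a design point the filters
depend on. The default start partitions the sorted values into k
equal-frequency bins and uses their moments - the deterministic,
agglomeration-style strategy reference mixture software uses in one
dimension. EM then converges to the natural local optimum in which an
isolated high-value cluster is described by a single component, which is
precisely what "remove the highest component" needs. An alternative
multi-start k-means++ search that hunts the global maximum is available
(`init = "kmeanspp"`), but on bulk-plus-outlier-cluster inputs the global
maximum-likelihood solution can *tile* a tight outlying cluster with two
or three near-identical components; dropping only the highest component
then removes a shard of the spurious class rather than all of it. That
behaviour is measurably worse for the filtering task, which is why it is
not the default. All fits are deterministic (given a seed, for the
randomised option); a test cross-checks the attained log-likelihood
against the reference mixture implementation in `mclust`.

## GO enrichment

Enrichment is rank-based: for each term of one domain (BP, CC or MF,
analysed separately) the continuous gene measure - omega for the selection
scan, signed log-p for expression - is compared between members and
non-members with a Mann-Whitney U test using midrank ties. The p-value is
exact (full enumeration over member-rank subsets) when both groups have
at most eight genes, otherwise a normal approximation with tie-corrected
variance and continuity correction. Benjamini-Hochberg adjustment is
applied within each domain at FDR 10%, and terms with fewer than five
measured genes are skipped (both configurable). The signed log-p measure
is `|log10 p|` with positive sign for upregulated and negative for
downregulated genes; p = 0 is clamped to the smallest positive double.
Unlike the published GO-MWU tool the annotation is taken as-is: no GO
graph propagation and no clustering of similar categories. Planted-truth
simulations do not need the hierarchy, and the flat test is the
statistical core those additions wrap.

## Expression stage

Size factors are median-of-ratios over genes observed in every sample,
rescaled to geometric mean one (a pseudo-reference over nonzero samples
is available when no such gene exists). The working transform is
`log2(count/factor + 1)` - a simple variance-flattening stand-in for
spline-based variance stabilisation, adequate for Manhattan distances and
marker scores. Differential expression uses a negative-binomial GLM per
gene with log link and size-factor offsets: full model with one mean per
species against an intercept-only null, compared by likelihood ratio
against chi-square with (species - 1) degrees of freedom. Dispersion is
gene-wise method of moments on normalised counts, estimated within
species, pooled by degrees of freedom, shared between the two fits, and
floored at 1e-8; it is inflated by the small-sample factor n/(n - g) for
the g estimated group means, without which the plug-in LRT is measurably
anti-conservative at these sample sizes (the null-calibration test holds
the 5% level to within twice its binomial standard error on 2,000 null
genes). None of the production DE machinery - dispersion shrinkage,
Cook's distance filtering, independent filtering - is reproduced; the
acceptance surface is simulation calibration, not numerical equality with
any specific tool. Pairwise contrasts reuse the same two-group LRT (one
degree of freedom) and report `log2((m2 + 0.5)/(m1 + 0.5))` of normalised
species means; for two species the LRT and the contrast are the same test,
which is asserted.

Ordination is classical scaling of Manhattan distances between samples on
the transformed matrix (the sum of log-fold differences across genes):
double-centre `-D^2/2`, eigendecompose, scale eigenvectors by the root
eigenvalues. Only positive-eigenvalue axes are kept; any negative
eigenvalue mass (Manhattan distances need not be Euclidean-embeddable) is
reported, and percent variance is taken over the positive part.

The outlier screen turns a judgement usually made by eye from heatmaps
into a rule: reproductively active females upregulate vitellogenin-like
genes in liver and distort species contrasts. Here each sample's marker
score is its mean transformed expression over a marker set, and a sample
is flagged when its score exceeds its species' median by more than 2
(log2 units, configurable). The count simulator plants exactly this
structure - half of the HFLA samples with a strong extra fold change on a
small marker set - and the tests require the screen to flag exactly the
planted subgroup and the affected contrast to lose DEGs after exclusion.

## Numerical choices and problem sizes

Defaults throughout are the pipeline's canonical thresholds: hit acceptance
1e-5 / 75% / 50%, dS mixture k = 3, omega mixture k = 4 with the (1, 3)
positive-selection bounds, GO FDR 0.10, DE p < 0.01 for the LRT count.
EM tolerance 1e-8, variance floor 1e-8, MCL convergence 1e-6 with
pruning at 1e-12, e-value weight cap 200. The test-suite and acceptance
runs use 120-300 simulated triplets, 300-codon genes for estimator
recovery, 25 replicates per omega class, and 800-2,000 genes for the
count-based checks - sizes at which every stochastic assertion holds with
a comfortable margin under its fixed seed while the whole suite stays
quick on a single CPU.

## Known limitations

Orthology is strictly one gene per species (no in-paralog resolution or
many-to-many groups); the MCL stage approximates FastOrtho rather than
reproducing its I/O; NG86 underestimates omega slightly when positive
selection is strong and divergence is deep; the expression skeleton does
not shrink dispersions, so per-gene power is below that of moderated
tools at equal sample size; and the GO stage ignores the term hierarchy.
These are deliberate scope boundaries: each replaced component sits
behind an interface (hit tables, omega tables, annotation tables) through
which production tools can be substituted.
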