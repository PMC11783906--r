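---
title: "Methods and design of panfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of panfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`panfam` characterizes a domain-defined gene family across a panel of
genome assemblies (a pangenome) instead of a single reference. This
vignette explains the models and procedures behind each stage, the
parameters that matter, the synthetic corpus the package validates itself
on, and the numerical decisions a maintainer should know about. No
empirical claim is made here beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The pipeline model

The unit of analysis is the **pangene** (orthologous gene group, OGG): a
cluster of corresponding family genes across genomes. The pipeline turns
per-genome inputs (assembly FASTA, GFF3 gene models, protein/CDS FASTA,
TE BED, tissue TPM tables) into pangene-level statements about
conservation, duplication mechanism, TE context, selection pressure,
expression divergence and subfamily membership. Stages run in dependency
order inside `run_pipeline()`; every stage is also exported as a plain
function so any step can be run, or cross-checked, in isolation.

### Domain scan and E-values

Family membership is defined by one conserved domain. The scanner builds a
position-specific scoring matrix (PSSM) from a seed alignment: columns
with more than 50% gaps are dropped, per-column amino-acid frequencies get
a +1 pseudocount, and scores are log2 odds against a uniform background.
Score-to-E-value calibration fits a Gumbel distribution (moment
estimators) to the maximum window scores of 1000 random background
sequences of length 200; a hit's E-value is the expected number of
exceedances, scaled by the ratio of windows scanned to windows in the
calibration. One best (lowest-E) hit is kept per sequence, ties resolved
to the leftmost envelope, mirroring the one-domain-per-gene convention.
Thresholds follow the field's standard practice: E ≤ 1e−5 and a domain
envelope of at least 30 aa (`min_domain_len`, inclusive boundary; an
envelope of 29 aa is rejected, 30 aa retained). Proteins shorter than half
the profile length cannot form an envelope; sequences between half and
full profile length are scanned with partial windows whose envelope is
clipped to the sequence, which is how short, partial family proteins
surface with envelopes below the profile length. Precomputed scans in
HMMER domtblout dialect can be injected through `read_domtblout()`.

Unannotated members are recovered by a six-frame ORF scan
(`scan_unannotated_regions()`): ATG-initiated, stop-bounded ORFs of at
least `min_orf_aa` = 60 residues outside annotated gene spans are
translated and scanned like proteins. This recovers single-exon genes
only; a member whose domain is interrupted by an intron cannot yield a
qualifying ORF and is reported as a multi-exon miss
(`hidden_recovery_report()`). That limitation is intentional: full
spliced-gene reconstruction is out of scope, and partial recoveries are
themselves informative (real genomic scans show exactly this behavior for
members conserved only across the domain).

### Clustering and conservation categories

Members are clustered greedily in order of decreasing protein length
(ties: ascending id). A member joins the first cluster, in founding order,
whose representative it matches at identity ≥ 0.95 and coverage ≥ 0.90,
else it founds a new cluster. Identity is identical aligned residues
divided by the *shorter* sequence's length (the CD-HIT convention — the
cited threshold names only the coverage denominator, "the longer
sequence", so the identity denominator was a design decision); coverage is
residue–residue aligned columns divided by the *longer* sequence's length.
Pairwise alignment is global with BLOSUM62 and affine gaps (open 10,
extend 0.5), computed by Biostrings. Because members are visited
longest-first, each representative is automatically the longest member of
its cluster (ties: smallest id). A full-linkage variant is available
behind `full_linkage = TRUE` for sensitivity analysis; the
representative-only rule is the default because it is what the clustering
tool being emulated does.

Categories derive from presence counts: core = present everywhere;
softcore = fraction ≥ 0.90 but not all; cloud = fraction ≤ 0.10; shell =
the open interval between. For 20 genomes this yields counts 20 / 18–19 /
3–17 / 1–2. "Line-specific" and "cloud" are treated as one category.
Systematic names sort pangenes by anchor position (chromosome, then
start) within category and number them continuously across categories in
the order CR → SC → SH → CL, zero-padded to width 3, so with 140 core
pangenes the first softcore is `…SC141`. The anchor is the representative
member's position in a user-designated reference genome; pangenes absent
there are anchored in the lexicographically first genome containing them —
the naming convention being emulated does not say how to anchor pangenes
missing from the reference, so this is the package's choice.

### Duplication typing

Per genome, an all-vs-all protein search (E ≤ 1e−5) keeps the top
`k = 5` subjects per query (ties: higher identity, then subject id;
self-hits excluded). The default engine shells out to NCBI `blastp` —
the practical choice for a whole proteome — while a native
Smith–Waterman engine (Biostrings, Karlin–Altschul E-values with BLOSUM62
gapped constants) serves small inputs and cross-engine tests. Gene ranks
are 0-based ordinal positions by start coordinate per chromosome, always
recomputed from coordinates. Collinear blocks are maximal chains of hit
pairs, strictly monotone in rank on both chromosomes (same or reversed
orientation), per-step rank gap ≤ 25 on each side, at least 5 anchors;
chains are extracted by O(n²) dynamic programming, best chain first.
`min_anchors = 5` and `max_rank_gap = 25` follow the emulated
classifier's documented defaults; the underlying publication is silent on
them. Labels apply the five rules in order, later overriding earlier:
singleton → dispersed (any hit) → proximal (same-chromosome rank
difference strictly between 1 and 20) → tandem (difference exactly 1) →
WGD/segmental (block anchor). Rank differences are only defined within a
chromosome, so cross-chromosome hits can yield only dispersed or, via
blocks, WGD/segmental.

### TE association

Gene windows are `[start − 2000, end + 2000)` clamped to the chromosome,
strand-agnostic. A TE counts for a gene iff it is flagged intact and
overlaps the window by ≥ 1 bp (configurable; the source convention states
no minimum, so the simplest compatible rule is used); intervals are
0-based half-open, so a TE starting exactly at the window end does not
count. A TE spanning two gene windows counts once per gene — the statistic
is per-gene. Genes of CNV pangenes (copy count varying across genomes,
including absence) are compared with genes of single-copy core pangenes by
a two-sided Welch t-test; the phrase "2-way t test" in the emulated
analysis is nonstandard and was interpreted as two-sided
unequal-variance, the conservative default.

### Selection (NG86)

Ka/Ks uses the Nei–Gojobori (1986) counting method. Site counting is
normalized so each codon position contributes exactly one site: the
synonymous fraction of a position is the share of synonymous changes among
the single-nucleotide changes that do not create a stop codon, giving
N + S = 3 × (comparable codons) exactly. Observed differences at codons
differing in k positions average the k! mutational pathways that avoid
stop codons, equally weighted (all pathways if every one passes through a
stop — a rare corner retained for totality). Proportions are
Jukes–Cantor corrected, Ka = −(3/4)·ln(1 − (4/3)·pN); pN or pS ≥ 3/4
makes the rate undefined. ω is reported missing when Ks = 0 (never
infinity), and such pairs are excluded from, but counted alongside, the
aggregates. Codon columns with a gap or ambiguity in either sequence are
excluded pairwise. NG86 was chosen because the toolchain being emulated
does not state its estimator and NG86 is closed-form and verifiable
against an independent pathway-enumeration oracle (the test suite asserts
agreement to 1e−9); the estimator name is recorded in the output. Codon
alignments come from back-translating protein alignments; for equal-length
member pairs at ≥ 80% identity the gapless alignment is used directly —
under the affine penalties used, gaps cannot improve an alignment with so
few mismatches — which avoids a large constant cost in the
dynamic-programming aligner. Group comparison reports medians (matching
the violin-plot annotation style of the emulated figure) with a Welch
t-test as printed there; a Mann–Whitney option exists behind a flag. Note
that ω̂ is a ratio estimator: at few substitutions per pair it is biased
upward (Jensen's inequality on 1/Ks), so group medians at a target ω of
0.8 sit somewhat above 0.8 while the core/dispensable contrast is
preserved. No outlier removal is performed anywhere, and pairs dropped for
undefined ω are reported.

### Expression divergence

Per pangene and tissue, TPM is summed over a genome's member copies,
then averaged across the genomes containing the pangene (presence-aware:
genomes lacking it are excluded, so removing such a genome provably
changes nothing). Transforms: normalized mean log2(TPM + 1); relative SD
log2(SD/mean + 1), defined as 0 when the mean is 0 (SD/mean is undefined
there, and a never-expressed pangene has no variability to report).
Profiles of normalized means are clustered by complete-linkage
agglomeration on Euclidean distances — the defaults of the heatmap
package used in the emulated analysis — cut into k = 3 clusters; rows are
sorted by pangene name first so results do not depend on input order
(with continuous data, distance ties have measure zero, so this suffices
for determinism). The tanglegram statistic counts leaf-pair inversions
between the phylogeny's and the dendrogram's leaf orders exactly,
normalized by C(n,2); no rotation optimization is applied — each tree
keeps its own order, which keeps the metric well-defined. Per-subfamily
transcriptional divergence is the variance of a subfamily's leaf-rank
displacement. Mean profiles (not per-genome profiles) feed the
clustering, matching the axis of the emulated heatmap.

### Phylogeny and subfamilies

Domain sequences of pangene representatives plus labeled reference
domains are aligned with MAFFT (deterministic for fixed input; the
package's thin wrapper preserves input order). Maximum-likelihood
inference with bootstraps is out of scope; instead distances are
Poisson-corrected p-distances, d = −ln(1 − p) with pairwise deletion of
gap columns (p capped at 0.95 to keep d finite), and the tree is
neighbor-joining via ape. NJ can produce slightly negative branch
lengths; they are clamped to zero so patristic distances stay
non-negative. Each unlabeled leaf takes the subfamily of its nearest
reference by patristic distance (ties: lexicographically smallest
reference id); leaves beyond `subfamily_max_distance` get an
"SF_like"-style unplaced label. Reference labels are user-supplied
(id → subfamily TSV); nothing is hard-coded. Enrichment of dispensable
pangenes per subfamily is a hypergeometric upper-tail test with
Benjamini–Hochberg correction across subfamilies.

## The synthetic pangenome

`simulate_pangenome()` emulates the study design the pipeline targets: N
related genomes carrying one focal family with controlled conservation
structure, plus everything downstream stages need. Defaults (all
overridable in `sim_config()`):

* 20 genomes × 3 chromosomes of 400 kb. Twenty is the panel size of the
  motivating study; three chromosomes suffice for cross-chromosome events
  at desk scale.
* 48 pangenes — 30 core, 4 softcore, 8 shell, 6 cloud — in 6 subfamilies.
  The category proportions mirror the motivating study's 140/12/29/20
  profile at reduced count (and the 18 dispensables match its
  selection-contrast group size); the full scale is reachable by
  configuration but the default keeps a complete pipeline run at a few
  minutes on one CPU.
* Presence counts per category are drawn uniformly from the integer
  ranges implied by the classifier boundaries (core 20, softcore 18–19,
  shell 3–17, cloud 1–2), so realized categories equal planned categories
  by construction.
* Sequence model: a 60-aa root domain; subfamily ancestors diverge 25%
  at the amino-acid level, pangene ancestors 8% further (within-subfamily
  flanks shared, giving between-pangene full-protein identity far below
  the 95% clustering threshold); members derive from their pangene
  ancestor CDS by 5 accepted substitution events at the category's target
  ω (0.2 core, 0.8 dispensable — the relaxation contrast to emulate), so
  member–representative identity stays ≥ 95% while Ka/Ks carries signal.
  Family proteins are 200 aa (domain at positions 71–130); background
  genes 80 aa.
* Genome layout: each chromosome is a run of "family slots" — 13
  background genes, the family gene, 13 more — so consecutive family
  genes sit 27 ranks apart. This exceeds both the proximal window (20)
  and the collinearity gap (25), which makes the truth labels of
  non-duplicated family genes unambiguous (dispersed) and prevents
  spurious family–family collinear chains. Subfamilies cycle across
  slots so same-subfamily genes are ≥ 54 ranks apart. Background gene
  density is therefore not a free aesthetic: it is what makes gene-rank
  semantics meaningful.
* CNV: 30% of pangenes receive events typed by
  `dup_event_rates` (dispersed 0.55, tandem 0.20, proximal 0.15,
  segmental 0.10 — dispersed-dominant, as observed in the emulated
  system). Tandem copies insert at rank offset 1, proximal at 3–12,
  dispersed on another chromosome away from same-subfamily genes,
  segmental as a copied block of the family gene plus its 5 following
  background genes (≥ 6 anchors, guaranteeing detection under the
  defaults). Segmental events are restricted to core pangenes by default
  (`segmental_core_only`), reproducing the observed association between
  large-scale duplication and strict conservation.
* TEs: intact-TE counts per gene window are Poisson with rate 1.48 for
  genes of CNV pangenes and 1.36 otherwise (the emulated means), placed
  entirely within the window; non-intact decoys (rate 0.2) exercise the
  intactness filter. Family windows of distinct slots are disjoint by
  construction; windows of tandem/proximal copies can overlap their
  source's, where spillover counting slightly inflates realized counts —
  visible only in those clusters.
* Expression: pangene base means are log-normal (meanlog 1.5, sdlog 1.2,
  i.e. typical TPMs of ~1–50); each pangene has an archetype (broad /
  tissue-specific / half-tissues, probabilities 0.4/0.3/0.3) creating
  exactly the three transcriptional cluster shapes the expression
  clustering should find; per-genome TPM is Gamma with
  CV(μ) = 1.2·(μ+1)^−0.4 + 0.15, a decreasing mean–CV link that encodes
  the higher-expression/lower-variability pattern.
* Annotation dropout: 5% of family genes (or an exact `n_hidden`) are
  removed from GFF3/protein/CDS/expression outputs but kept in the
  genomic sequence, exercising the ORF scan. Implanted genes are
  bracketed by 9-nt stop-codon insulators so that the stop-bounded ORF of
  a hidden gene is exactly its annotated span; without them, random
  in-frame upstream ATGs would shift ~25% of recovered coordinates.
  A hidden gene whose start codon happens to be mutated away by the
  divergence process is unrecoverable — a rare, accepted miss.

Determinism: every stage derives an independent sub-seed from the root
seed, and identical configurations produce byte-identical corpus files;
the pipeline in turn produces byte-identical reports (checked by MD5
manifest in the tests).

What the generator does **not** emulate: gigabase chromosomes and real
repeat landscapes, multi-exon gene structure (all simulated genes are
single-exon, so the ORF scan's multi-exon limitation is exercised only by
constructed fixtures), sequencing or assembly error, annotation noise
beyond clean dropout, phylogenetic structure among genomes (members
diverge independently from their pangene ancestor), and TE biology beyond
Poisson placement. Passing tests therefore demonstrate algorithmic
correctness and the recoverability of planted effects at realistic
parameter values — not performance on real assemblies, where domain
models, annotation quality and repeat content are all harder.

## Problem sizes used in validation

The test suite validates operations on fixtures of tens to hundreds of
genes with brute-force oracles (all-pairs alignment clustering up to ~50
members × 20 seeds; NG86 pathway enumeration on 100 random 50-codon
pairs; interval and inversion counting oracles), recovers planted effects
at the scenario sizes that matter (TE contrast at group sizes 256 vs
1451; selection contrast with 30 pangenes per group × 20 replicates;
expression coupling over 40 pangenes × 20 replicates), and runs the full
default-scale pipeline twice to assert byte-identical reports and ≥ 95%
truth agreement for clustering, categories, duplication labels and
subfamilies. `scripts/acceptance.R` repeats the default-scale run from
scratch and emits all measured quantities as JSON.

## Known limitations

* The ORF scan recovers single-exon members only; multi-exon hidden genes
  are reported as misses, and partial-domain ORF fragments can surface as
  members (as partial sequences do in real genomic scans).
* NG86 ω̂ is biased upward at low divergence; contrasts are reliable,
  absolute values at few substitutions are not.
* The native homology engine's Karlin–Altschul constants are nominal
  BLOSUM62 gapped values, adequate for the near-identical fixtures it
  serves; whole-proteome work should use the BLAST engine.
* Greedy clustering is order-dependent by specification (longest-first,
  first-matching-cluster); the brute-force oracle in the tests re-executes
  exactly that rule, not an optimal partition.
* The collinearity chain extraction is greedy (best chain first) and does
  not attempt overlapping-block resolution; at pangenome-family scale
  anchors are sparse and this is immaterial.
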