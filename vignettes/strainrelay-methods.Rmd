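---
title: "Methods: strain-resolved mother-to-neonate transmission analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-resolved mother-to-neonate transmission analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainrelay)
```

# The analysis

strainrelay re-implements, as a reusable and tested pipeline, a
strain-resolved analysis of paired mother-neonate gut metagenomes across
delivery modes (vaginal delivery, VD; caesarean section, CSD; caesarean
section with small-for-gestational-age neonates, CSD_SGA). The pipeline has
five analytical stages, each usable on its own:

1. **Artefact removal** in low-biomass samples against a negative control;
2. **Genome binning and cross-sample linking** via single-copy marker genes;
3. **Strain-sharing calls** from cophenetic distances on marker trees;
4. **Population genomics**: intra-population nucleotide diversity
   ($\pi$) and the fixation index ($F_{ST}$) from allele-count pileups;
5. **Functional analysis**: KO profiles, rank-based differential abundance,
   and pathway/genome enrichment statistics.

A seeded synthetic-cohort generator produces inputs with known ground truth
for all five stages, so the whole pipeline is testable without any external
data.

# Artefact removal

Low-biomass samples (neonatal stool in the first days of life) are prone to
artefactual DNA introduced during extraction and library preparation. The
removal procedure combines two mechanisms against a negative-control
sample processed with the same reagents:

* **k-mer screening**: a study contig is discarded when at least 90% of its
  canonical 31-mers occur in the control contigs. This is the contig-level
  analogue of mapping study reads against control contigs (no read data
  exists in this artifact; thresholds are exposed as parameters).
* **Joint binning**: control and sample contigs are embedded together by
  genomic signature (canonical tetranucleotide frequencies, 136 dimensions
  after reverse-complement collapsing, centered-log-ratio transformed and
  projected onto the first two principal components) and clustered with
  DBSCAN. Every bin with total length strictly below 10 Mbp that contains
  strictly more than 0.01% of the control sample's total contig length is
  flagged as a putative artefact genome, and its member contigs are removed.
  Both inequalities are deliberately strict.

Numerical choices: the CLR pseudocount is 3e-3 on tetranucleotide
*frequencies*; a much smaller pseudocount lets absent 4-mers dominate the
log-ratio geometry of short contigs with noise, visibly degrading cluster
compactness. The PCA projection uses a fixed sign convention (each
component is flipped so its largest-magnitude loading is positive), which
makes the default embedding exactly reproducible. A stochastic
neighbour-preserving alternative (seeded Sammon mapping from a random
initial configuration) is available for fidelity experiments; it is not the
default because unit tests should be exact. DBSCAN's `eps` defaults to the
95th percentile of 4-nearest-neighbour distances — a declared heuristic,
not a value taken from any study — with `min_points = 5`.

An rRNA-exclusion hook (`exclude_ids`) exists for real data; synthetic
contigs carry no rRNA, so it is a no-op in simulations.

# Genome binning and linking

Curated contigs of each sample are clustered into genome reconstructions
with DBSCAN on the 2-D composition embedding augmented with a coverage
axis, `coverage_weight * log10(coverage)`. The embedding is kept in its
native CLR units rather than standardized per axis: standardizing inflates
pure-noise directions to unit variance and erases the coverage signal
exactly when composition is uninformative. The default
`coverage_weight = 5` makes a ten-fold coverage difference comparable to a
typical between-genome composition distance. Bins shorter than
`min_bin_length` are discarded; the 100 kb default suits real prokaryotic
assemblies and is scaled to a quarter of the simulated genome length inside
the pipeline defaults (a 40 kb toy genome cannot meet a 100 kb floor).

Completeness of a bin is the fraction of the 35 single-copy marker-gene
families with at least one hit among its contigs. The marker catalogue is
modelled abstractly as families 1..35; real HMMs are not shipped, and
real-data users attach their own marker annotations.

Single-copy families also drive a contamination-aware refinement. Two
genomes whose signatures happen to superimpose in the 2-D projection of one
sample can end up in a single chimeric bin; such a bin carries *duplicated*
single-copy families whose two copies fall into different marker clusters.
Bins with at least three duplicated families are split by marker evidence:
communities are first detected on the unambiguous bins, each marker cluster
is mapped to its majority community, and the chimeric bin's contigs follow
their markers (marker-less contigs follow the largest split group). Without
this step a single recurrent composition collision bridges two genome
communities cohort-wide, which is also why real workflows treat duplicated
single-copy markers as a contamination signal.

Marker proteins are clustered at 97.5% identity (inclusive) by greedy
incremental clustering in order of decreasing length (ties broken by
identifier), each sequence joining the first cluster whose representative
it matches. Identity is matches over alignment length with gaps counted as
mismatches — declared explicitly because word-filter heuristics of
production clustering tools are not reproduced. Bins become nodes of an
undirected graph whose edge weights count the marker clusters shared by two
bins; communities detected by greedy modularity maximization
(`cluster_fast_greedy`) are the putative cross-sample genomes. The greedy
cut is never allowed to score below the trivial single-community partition
(a correction that matters only for degenerate graphs such as cliques).
Communities containing more than one bin from a single sample are reported
as ambiguous — the automated counterpart of manual inspection.

# Strain sharing

For each genome community (clade), one marker repertoire represents each
genome bin (`genome_based` evidence) or each sample's pooled markers
(`read_based` evidence — the counterpart of read-based strain
reconstruction, without reproducing any database-driven internals).
Pairwise distances are total mismatches over total compared sites across
shared marker families; a neighbour-joining tree is built (negative branch
lengths clamped to zero with the deficit moved to the sister branch) and
its cophenetic matrix taken.

A neonate is called to share a strain with its mother when the cophenetic
distance between the neonatal and maternal markers is **strictly** less
than the distance to the markers of any other individual; ties are not
shared. When an individual contributes several samples or bins (days 1, 3,
5), the minimum distance over them represents the individual. The margin
(distance to the nearest other individual minus distance to the mother) is
exported with every call so users can apply their own evidence thresholds;
no quantitative "level of evidence" scale is imposed.

# Population genomics

Allele-count pileup columns are the atomic unit: reads are never
represented individually, because every downstream formula consumes allele
counts only. The stage applies, in order:

1. **Qualification**: a genome-sample combination enters the analysis only
   with median coverage $\ge$ 20x, breadth $\ge$ 40%, and completeness
   strictly above 65% (median coverage is computed over covered positions;
   breadth is the covered fraction of genome positions).
2. **Downsampling** to a median coverage of 20x by binomial thinning of
   every allele count with probability target/median — a thinning model
   rather than exact read subsampling, again because reads are not
   represented.
3. **SNV filters**: a non-major allele is retained when supported by at
   least 4 reads **and** reaching an allele frequency of at least 1%; both
   thresholds inclusive.
4. **Common loci**: all statistics are restricted to loci covered in every
   compared sample of the same genome, making intra- and inter-population
   diversities commensurable.

Per locus $l$ with allele frequencies $f_a$,
$\pi_l = 1 - \sum_a f_a^2$ (plugin estimator, reads drawn with
replacement) or $\pi_l = \sum_{a \ne b} c_a c_b / (n(n-1))$ (unbiased,
without replacement). $\pi$ is the mean of $\pi_l$ over **all** loci in the
set, monomorphic loci contributing zero, so $0 \le \pi < 1$ per site. The
between-sample diversity is $1 - \sum_a f^{(1)}_a f^{(2)}_a$, and

$$F_{ST} = 1 - \frac{(\pi_1 + \pi_2)/2}{\pi_{between}},$$

all three terms averaged over the same loci. The plugin mode is the default
for internal consistency — it makes $F_{ST}$ of two identical samples
exactly zero — while the unbiased mode is provided because the definition
of $\pi$ as a property of read pairs admits the without-replacement
reading. The mode is recorded in every output row. A 95% minimum alignment
identity filter from read mapping is honoured as a pass-through flag:
synthetic pileups are generated per genome, so cross-species read bleed
cannot arise here.

# Functional analysis

A gene receives the KO with the highest bit score among its candidates iff
that score strictly exceeds $\log_2$(number of target genes); ties break to
the smallest KO identifier. Read counts are summed per KO and
row-normalized per sample.

The original study fitted a negative-binomial Wald model with day
covariates for differential KO abundance. That engine is **deliberately not
reproduced**; a stratifiable rank-based test replaces it: per KO, two-sided
Wilcoxon rank-sum tests of VD versus CSD and VD versus CSD_SGA on relative
abundances pooled over days 3 and 5, BH-adjusted across KOs within each
comparison. The combination rule is kept verbatim: a KO is differentially
abundant when the adjusted p is below 0.05 in at least one comparison *and*
the direction of change agrees across comparisons. Exact rank-sum
distributions are used for combined sample sizes up to 20 without ties;
otherwise the normal approximation with tie correction.

Pathway enrichment of a DA set is the one-sided hypergeometric upper tail
(including the observed overlap) against the universe of all detected KOs,
BH-adjusted across pathways. The pipeline runs it per direction of change
(VD-enriched and VD-depleted DA KOs as separate draw sets, both reported):
because relative abundances are compositional, raising one guild's
abundance necessarily lowers every other KO's share, so a pooled draw set
mixes two anti-correlated signals and dilutes both — the standard
up/down-set split from expression analysis applies unchanged. Genome-level enrichment uses Fisher's exact
test (two-sided, sum of hypergeometric probabilities not exceeding the
observed table's) with the sample odds ratio $ad/bc$; zero cells trigger a
flagged Haldane 0.5 correction. Jensen-Shannon divergence uses base-2
logarithms (range [0, 1], square-root distance selectable); Shannon
diversity uses natural logarithms (the vegan convention); Pielou evenness
is $H/\ln(\text{richness})$, undefined for a single taxon. Gram-stain
fractions are aggregated per genus from a user-supplied table; genera
without a label are reported as unknown and never folded into the labelled
fractions.

# The synthetic cohort generator

`cohort_config()` / `generate_cohort()` draw a complete paired cohort with
machine-readable ground truth. The defaults define the simulated study
conditions:

* **Design**: 4 pairs per group (VD, CSD, CSD_SGA); mothers sampled once
  before delivery (faecal), neonates at days 1, 3, 5; one cell-culture
  negative control. Four pairs per group give an 8-vs-8 comparison when
  days 3 and 5 are pooled — about the smallest design in which an exact
  rank-sum test can clear a BH-adjusted 0.05 across ~120 KOs.
* **Genomes**: 12 genomes of 40 kb in four classes (4 Gram-negative
  enteric, 3 Gram-positive enteric, 2 skin-associated, 3 contaminant).
  Each genome is generated from its own order-1 Markov transition matrix
  (class GC plus a log-normal perturbation, `signature_sd = 0.5`), giving
  every genome a distinct oligonucleotide signature — the property
  composition-based binning exploits in real assemblies. Contaminant
  genomes sit at GC 0.68 with a deliberately tight within-class spread,
  reflecting the high-GC Betaproteobacteria that dominate real reagent
  contamination. 40 kb at the 5 kb median contig length yields ~8 contigs
  per genome, enough for density-based clustering to form stable clusters.
* **Strains**: each individual's strain is an independent per-site mutant
  of the species reference at rate `strain_divergence / 2` (so two
  unrelated strains differ at about `strain_divergence` = 1% of sites).
  Transmission copies the maternal strain with a small additional
  substitution rate (1e-4). Only a quarter of marker-gene substitutions
  change the protein (`nonsyn_fraction`), reflecting purifying selection on
  single-copy markers; this keeps unrelated strains' marker identities
  (~99.2%) above the 97.5% clustering threshold while separating them
  clearly from transmitted strains (~99.99%).
* **Within-host diversity**: 0.4% of sites are polymorphic per host with
  folded-Beta(1.5, 8) minor-allele frequencies. Transmission perturbs
  allele frequencies on the logit scale with s.d. `bottleneck_shift = 1.5`;
  day-to-day drift uses s.d. `drift_shift = 0.15`. No study provides a
  quantitative bottleneck model, so these are free parameters chosen once
  to reproduce, qualitatively, the observed ordering that maternal-neonatal
  fixation indices exceed within-neonate (day 3 vs day 5) fixation indices;
  the ordering is robust to the exact values because the bottleneck
  perturbation is an order of magnitude larger than daily drift.
* **Ecology**: mothers carry enteric genomes with high probability;
  transmission probabilities depend on delivery group and genome class
  (enteric strains flow in VD, skin strains in CSD); a small environmental
  acquisition probability (0.05) plants strains that are present in the
  neonate but *not* maternally derived — the hard negatives for the
  sharing criterion. Contaminants make up 15% of low-biomass (neonatal)
  samples, 2% of maternal samples, and 100% of the control.
* **Function**: 120 KOs; each genome carries 40; a 9-KO LPS-like pathway is
  restricted to Gram-negative genomes, whose abundance in VD neonates is
  multiplied by `lps_effect_size = 3`.
* **Coverage**: per-genome depth is Poisson with mean
  `depth_mean[body site] * relative abundance` (faecal default 300x, so a
  genome at 10% relative abundance sees ~30x — above the 20x gate).

Ground truth records transmissions, environmental acquisitions, contaminant
contigs, contig provenance, true allele frequencies, true $\pi$ (by the
plugin estimator), the planted DA KOs and the Gram table.

**What the generator does not emulate**: reads and read-level errors
(pileups are multinomial draws from true frequencies with no sequencing
error), indels and rearrangements, rRNA, real marker HMMs, horizontal gene
transfer, within-sample strain mixtures of one species, twin pairs, feeding
regime and antibiotic covariates, and 16S amplicon data. Passing tests
therefore demonstrate that the *machinery* implements its definitions and
recovers planted signal under this model — not that the thresholds are
optimal for any particular real data set.

# Pipeline wiring and evaluation

`run_pipeline()` executes simulate, decontaminate, bin/link, strain
sharing, popgen and functional analysis, and evaluates calls against the
ground truth (precision/recall on contig removal, co-community bin pairs,
and (pair, genome) sharing calls). Two wiring notes:

* On real data, pileups are indexed by the same reconstructed genomes whose
  completeness gates the popgen stage. The synthetic cohort's pileups are
  indexed by true genome identifiers, so the pipeline maps communities to
  pileup genomes by majority contig provenance — evaluation wiring, not
  part of the method.
* The popgen stage compares only samples within the same mother-neonate
  pair (the comparisons the analysis interprets), not all sample pairs.

The type-I error of the differential machinery is checked under a fully
null configuration: identical transmission probabilities across groups
**and** unit LPS effect. Nulling only the effect size would leave real
compositional differences between groups (different genome repertoires by
delivery mode), which the test would correctly — not spuriously — detect.

Problem sizes used in the shipped tests: 20 cohorts at the default
configuration for the recovery properties, about 1,000 null KOs for the
type-I check, 500 random pileup columns for the estimator oracles. The
whole default synthetic pipeline runs in well under a minute per cohort on
a single CPU.

# Known limitations

* DBSCAN parameters are heuristics; on real assemblies users should
  inspect embeddings and set `eps`/`min_points` per sample.
* The 2-D composition projection can superimpose genomes with similar
  signatures; the coverage axis resolves most but not all collisions, and
  merged bins surface in the ambiguity report.
* The exact estimator variant used by the original popgen tooling
  (replacement handling, locus denominators) is not published; both modes
  are exposed rather than guessing, and the mode is recorded in outputs.
* `read_based` evidence derives clade membership from the marker-cluster
  communities; with real data a marker database would define clades
  instead.
* The rank-based differential test is less powerful than a parametric
  count model on real data with covariates; it was chosen for robustness
  and exactness at small n, and the decision is recorded here rather than
  hidden.
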