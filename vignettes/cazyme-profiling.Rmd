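---
title: "Profiling carbohydrate degradation capacity in MAG communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling carbohydrate degradation capacity in MAG communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cazyprofiler` profiles the polysaccharide-degradation capacity of a
community of metagenome-assembled genomes (MAGs): which taxa can cleave
which macroalgal glycans, how that capacity is organized into gene
clusters, and how co-varying MAGs complement each other. This vignette
explains the models behind each stage, the tunable parameters, the
synthetic test bed, and the design decisions taken where the published
practice leaves the procedure under-specified.

## Consensus annotation model

Carbohydrate-active enzyme (CAZyme) annotators disagree: profile HMMs,
k-mer classifiers and similarity searches each have characteristic error
modes. The consensus rule treats the three streams (labelled HMMER, eCAMI
and DIAMOND) as exchangeable votes: a protein receives a family call iff
at least two streams agree on the family, after collapsing subfamily
labels (GH13_10 → GH13) because streams report at different granularity
and downstream analyses operate at family level. The reported label comes
from the highest-priority agreeing stream — HMMER, then eCAMI, then
DIAMOND — reflecting the relative specificity of the methods. With three
streams, two disjoint agreeing pairs cannot occur, so the priority rule
resolves every reachable configuration; when a single stream reports
several families, any intersection with another stream counts as
agreement and the priority stream's best e-value breaks ties.

Acceptance filters (all thresholds are `pipeline_config()` fields,
stored as fractions of the database target):

* every hit must pass an e-value cutoff of 0.001 at load time;
* EC-number annotations: coverage ≥ 0.40 and identity ≥ 0.30 (both
  inclusive — the rule is "at least");
* sulfatases: coverage ≥ 0.50, identity ≥ 0.30, and the protein must
  carry the formylglycine-dependent sulfatase domain PF00884, the
  structural signature of the S1 family;
* MAG quality: completeness ≥ 50% (inclusive) and contamination < 10%
  (strict, following the "less than" phrasing of the MIMAG
  medium-quality tier).

Consensus calls are monotone in evidence: removing a stream can only
remove or preserve calls, and raising any threshold can only shrink the
accepted set. Both properties are enforced by tests.

## Substrate catalog

The mapping from CAZy families, EC numbers, sulfatase S1 subfamilies and
mannitol-pathway genes to the nine substrate panels (alginate, laminarin,
FCSP, carrageenan, agarose, galactan, starch, sulfatases, mannitol) ships
as a versioned TSV (`inst/extdata/substrate_catalog.tsv`): the mapping is
curation, i.e. data, not code, and edits should be diffable. Entries are
flagged `dedicated` when unambiguous for a single substrate (PL6 is an
alginate lyase; GH150 a carrageenase) and carry a molecular-weight class:
HMW for endo-acting, polymer-cleaving activities (guluronate-specific
alginate lyases, glucan endo-1,3/1,6-β-glucosidases, carrageenases,
agarases, fucosidases acting on the fucan backbone), LMW for exo-acting
oligomer consumers (β-glucosidases, α/β-galactosidases, oligo-alginate
lyases). When a call carries an accepted EC number, the EC's weight class
overrides the family's, since EC resolution distinguishes endo from exo
isoforms within one family. The catalog covers the substrate scope of
macroalgal diets only; it makes no completeness claim against the live
CAZy database. The "galactan" panel aggregates the LMW galactosidase
activities downstream of FCSP/carrageenan/agarose degradation.

Mannitol capability is a pathway call, not a single gene: the M2DH route
requires mannitol 2-dehydrogenase *and* fructokinase; the PTS–M1PDH route
requires a mannitol phosphotransferase component *and*
mannitol-1-phosphate 5-dehydrogenase. A MAG may carry both.

The capability matrix sets a polysaccharide cell TRUE iff at least one
accepted call maps (possibly ambiguously) to that substrate — a MAG row
is the union of its calls' substrate sets. Ambiguous families therefore
light several panels; disambiguation is deliberately reserved for cluster
context (below). The sulfatase panel is driven by accepted sulfatase
calls and the mannitol panel by complete routes; a sulfatase's substrate
tags (FCSP vs carrageenan) annotate the call but do not light the
polysaccharide panels, which are reserved for glycoside-cleaving
evidence.

## Cluster detection and substrate inference

Polysaccharide-utilization loci co-locate CAZymes with transporters and
regulators. The published pipelines delegate detection to dbCAN's CGC
output with unstated parameters, so the rule is declared here explicitly
and mirrors the CGCFinder default: signature genes are CAZymes,
transporters (TC), transcription factors (TF) and signal-transduction
proteins (STP); a cluster is a maximal run of signature genes in which
consecutive signature genes are separated by at most `cgc_max_gap = 2`
non-signature genes, containing at least one CAZyme and at least one
non-CAZyme signature gene. Clusters never span contigs. Strand is
ignored — such loci are frequently mixed-strand and no strand rule is
stated in practice. Detection is validated against a brute-force oracle
that enumerates all windows and keeps maximal valid ones, exhaustively
over every role string up to length 12.

A cluster is *degradative* when it holds at least two members whose
mechanism class is GH, PL or CE. Binding modules (CBM),
glycosyltransferases (GT) and auxiliary activities (AA) never count: they
bind or build rather than cleave.

Substrate inference uses two kinds of evidence, applied to degradative
clusters only:

* **dedicated** — a member family unambiguous for one substrate assigns
  it directly;
* **colocalization** — an ambiguous family's candidate substrate is kept
  iff at least one *other* member family supports the same substrate
  (e.g., GH16 + GH3 → laminarin: an endo-1,3(4)-β-glucanase with a
  β-glucosidase; GH16 + GH86 → agarose, the dedicated agarase resolving
  GH16's ambiguity).

Surviving multi-substrate assignments are reported multi-label rather
than silently dropped, and tallies count such clusters once per
substrate. Clusters with no resolvable substrate stay unclassified.
Whether published per-genus tallies counted multi-substrate clusters once
or per substrate is unstated; the `multi` flag makes either tally
recomputable.

Per-taxon summaries report totals and per-MAG means ± SD, with the mean
taken over **all** MAGs of the taxon, including those with zero clusters
— the convention that makes a printed per-genus total of 73 clusters over
20 MAGs correspond to a mean of 3.65.

## Community statistics

CAZyme density defaults to calls per 1000 genes rather than per Mbp: the
per-gene unit is robust to genome incompleteness (both units are
supported; the published figure does not state which was used). Class
comparisons use the two-sided Wilcoxon rank-sum test as implemented in
`stats::wilcox.test`: exact for small untied samples, tie-corrected
normal approximation with continuity correction otherwise — the exact
small-sample path reproduces enumeration oracles (e.g., p = 0.1 for
{1,2,3} vs {10,11,12}), and the approximation handles ties at realistic
sizes.

Bray–Curtis dissimilarity is computed with `vegan::vegdist` on per-family
count vectors normalized by gene count (a "density composition"; raw
counts are available). BC is not a metric — no triangle inequality is
asserted — and a pair of all-zero profiles has no defined dissimilarity:
such pairs are returned as NA with a warning, never silently 0.

Per-genus section summaries use the Kruskal–Wallis chi-square
approximation with tie correction; when every value is tied the statistic
is 0 and p = 1 by definition (the tie-correction formula degenerates).
Raw p-values are reported, as is conventional for these per-genus
screens, with a Benjamini–Hochberg column alongside for transparency.

## Co-abundance analysis

Pairwise Pearson correlations of MAG relative abundances are computed
across all samples (fish × sections pooled), with two-sided p-values from
the t transform and p = 0 at |r| = 1. Constant-abundance MAGs are
excluded with a warning. The correlations are computed on closed
(relative) data exactly as practitioners report them; no centred
log-ratio transform is applied. This is a documented caveat, not an
oversight: closure induces spurious structure — in particular, when a
co-varying block dominates the composition, the remaining MAGs co-vary
through the shared denominator, and within-block correlations are
attenuated. The synthetic fixtures used to validate block recovery
therefore embed planted blocks as a minor fraction of a larger community.

Group delineation (the published heatmaps show blocks without naming a
method) is declared as: average-linkage hierarchical clustering on 1 − r
cut at 0.7, then connected components of significant positive edges
(p ≤ 0.05, r ≥ 0.3) within each cut cluster, keeping components of ≥ 2
MAGs. All four knobs are configuration fields. Groups are labelled
A1, A2, … when IV-enriched and B1, B2, … when stable or V-enriched
(mean member log10 fold change below −0.1 / above +0.1 / between),
ordered by summed relative abundance; the output is invariant to MAG
input order. Fold changes use
log10((mean_V + ε)/(mean_IV + ε)) with ε = 0.01 percentage points —
below any displayed abundance, avoiding infinities — and MAGs absent
from both sections are omitted with a note.

## Expression summaries

Relative expression is a within-category share: per gut section and
category (CAZymes, sulfatases, CAZymes within clusters), transcript
counts are summed per taxon class and normalized to 1 across classes.
No length normalization is applied by default because the quantity of
interest is a share of category transcription, not an absolute rate;
whether published shares were within-category or over all transcripts is
unstated, and counts are emitted alongside fractions so either can be
recomputed. CGC-member CAZymes are a subset of the CAZyme category, so a
gene can contribute to both. Cluster selection takes, per sample, the
minimal set of top-share substrate-assigned clusters whose cumulative
share reaches the upper quarter (quantile 0.25) of total cluster
expression, with boundary ties all included — making the selection
invariant to cluster order and to count rescaling; a cluster selected in
any sample of a section is reported for that section.

## The synthetic community generator

The generator is first-class, tested code: it emits the full on-disk
bundle (GFF3 gene table; three-stream CAZyme hits; sulfatase, domain and
mannitol evidence; MAG metadata; abundance, sample and transcript tables)
plus ground truth, deterministically from a seed.

What it emulates, and the defaults:

* **Community shape** — 68 MAGs split 31 Bacteroidia / 23 Clostridia /
  5 Bacilli / 9 across five minor classes, with genus structure
  (20 of the Bacteroidia are *Alistipes*-like). Completeness is drawn
  uniformly in [75, 99.5]% and contamination in [0, 6.4]%, the quality
  window of a retained MAG set; both ranges are configurable to exercise
  rejection.
* **Substrate guilds** — each class carries a guild: Bacteroidia degrade
  both brown- and red-algal substrates (eight panels plus sulfatases);
  Clostridia are brown-algae-biased; Bacilli and Gammaproteobacteria are
  narrow; the Desulfobacteria MAG has no degradative capacity (an
  all-false capability row). Family choices are constrained so that a
  planted ambiguous family's substrate set never leaves the MAG's guild,
  which is what makes exact capability recovery a meaningful test.
  Singleton planting is tilted toward exo-acting (LMW) enzymes, which
  dominate real gut communities, with rarer endo-acting (HMW) capacity.
* **Clusters** — degradative clusters (two to three substrate-consistent
  CAZymes plus a transporter, sometimes a regulator, gaps ≤ 2) at a
  Poisson rate of 2 per guild MAG, plus "weak" one-CAZyme clusters at the
  same rate that must never pass the degradative bar. Planted features
  are separated by more than the gap limit so they can never merge, and
  background transporters are placed away from CAZymes — detection
  must recover exactly the planted set.
* **Annotator noise** — each stream independently reports a uniformly
  random wrong family with probability `label_noise` (and drops out with
  probability 1 − `annotator_agreement`). This is the simplest mechanism
  that exercises the ≥ 2-agreement rule and admits a closed-form check:
  with noise p and L wrong labels, P(correct) = q³ + 3q²p,
  P(error) = 3p²/L(1 − p/L) + p³/L² (two streams hitting the same wrong
  label), and the remainder is no-call. Observed rates match within
  three binomial standard errors at p = 0.1 over > 1000 proteins.
* **Abundances** — per-MAG lognormal baselines with class-specific means;
  MAGs in a co-abundance block share a per-sample lognormal latent factor
  (sd 0.8 by default); a block's enriched section receives a
  multiplicative shift; independent per-MAG gamma noise (sd 0.3) is
  applied before closure to 100% (closure of independent gammas is the
  Dirichlet mechanism). The default plan plants six blocks — two
  IV-enriched A-style and four B-style — mimicking a two-section hindgut
  gradient.
* **Transcripts** — negative-binomial counts (dispersion 5) with
  class-by-section multipliers that make the hindgut chamber (section V)
  Bacteroidia/Clostridia-dominated.

What it does **not** emulate: nucleotide or protein sequences, read-level
error, assembly fragmentation or chimerism, incomplete gene models,
correlated annotator errors (real streams fail on the same hard
proteins), phylogenetic signal in guild composition, and compositional
zeros from shallow sequencing. Passing the recovery tests therefore shows
the pipeline's logic is correct under its stated assumptions, not that
those assumptions hold for any particular real dataset.

## Numerical choices and degenerate inputs

* Thresholds are inclusive (≥) except contamination (<); the boundary
  convention is asserted at the exact boundary values.
* Coordinates are 1-based inclusive everywhere (GFF3 convention); no
  internal offset conversions exist.
* All randomness lives in the generator; analysis stages are seed-free,
  and re-running the pipeline on identical inputs yields byte-identical
  primary TSV outputs (the run log additionally echoes the configuration,
  including the generation seed).
* Degenerate inputs have defined behaviour: header-only gene tables parse
  to empty tables; empty call sets yield zero-count summaries; all-tied
  Kruskal–Wallis inputs give p = 1; all-zero Bray–Curtis pairs give NA
  with a warning; constant-abundance MAGs are excluded from correlation
  with a warning; fold changes omit MAGs absent from both sections.
* Tie-breaks are deterministic: consensus ties resolve by source priority
  then best e-value; expression selection includes boundary ties; group
  ordering is by summed abundance with a lexicographic fallback.

## Test-bed problem sizes

The validation suite exercises: the full default 68-MAG, 2000-genes/MAG
community for exact recovery (capability, clusters, pooled counts) and
for the noisy-consensus binomial check; a 10-MAG, 300-genes/MAG bundle
for pipeline determinism; exhaustive role-string sweeps to length 12 for
cluster detection; exact enumeration oracles at n ≤ 8 for the rank tests;
30-MAG communities with planted 5 + 4 blocks over 12 samples for
co-abundance recovery; and 500-replicate power simulations (lognormal
densities, sdlog 0.5, two-fold shift at 20 MAGs per class; per-genus
shifts of 15 percentage points with between-fish sd 6 at 6 fish). These
sizes were chosen as the smallest at which each property is
non-trivially exercised.

## Known limitations

* The substrate catalog is a reconstruction scoped to macroalgal diets;
  families outside it classify as unmapped rather than failing.
* Correlation on closed data conflates biological co-abundance with
  compositional coupling; group labels describe covariation, not
  interaction mechanisms.
* Cluster substrate inference sees only family-level evidence; it cannot
  distinguish isoforms within a family without an accepted EC number.
* The consensus rule assumes stream errors are independent; correlated
  errors would inflate confident wrong calls relative to the closed form.
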