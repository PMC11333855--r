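# cazyprofiler

Carbohydrate-degradation profiling of metagenome-assembled genomes (MAGs)
from gut communities that ferment macroalgae.

Marine herbivorous fish such as the Silver Drummer carry dense hindgut
communities that break down brown-algal polysaccharides (alginate,
laminarin, fucose-containing sulfated polysaccharides, mannitol) and
red-algal galactans (carrageenan, agarose, floridean starch) into the
short-chain fatty acids that feed the host. Determining *which* community
members can degrade *what* requires stitching together several analyses
that are usually scripted ad hoc. This package implements that pipeline as
tested, reusable functions:

1. **Consensus CAZyme annotation.** Per protein, three annotation evidence
   streams (profile HMM "HMMER", k-mer classifier "eCAMI", similarity
   search "DIAMOND") are merged: a family *F* is called iff at least two
   streams agree (after collapsing subfamily labels such as GH13_10 to
   GH13), with the reported label taken from HMMER first, then eCAMI, then
   DIAMOND. EC numbers are accepted only at target coverage ≥ 40% and
   identity ≥ 30%; sulfatase calls (SulfAtlas S1 subfamilies) require
   coverage ≥ 50%, identity ≥ 30% and the formylglycine-dependent
   sulfatase domain PF00884. All hits pass an e-value cutoff of 0.001.
2. **CAZyme gene clusters (CGCs).** A cluster is a maximal run of
   signature genes (CAZyme, transporter TC, transcription factor TF,
   signal-transduction protein STP) with at most 2 intervening
   non-signature genes, holding ≥ 1 CAZyme and ≥ 1 non-CAZyme signature
   gene. Clusters with ≥ 2 degradative CAZymes (GH/PL/CE) are flagged
   degradative; substrates are inferred from dedicated families (e.g.,
   PL6 → alginate) and from co-location of complementary activities
   (e.g., GH16 endo-glucanase + GH3 β-glucosidase → laminarin).
3. **Community statistics.** Per-MAG CAZyme density (per 1000 genes or per
   Mbp), Wilcoxon rank-sum comparisons between taxon classes, Bray–Curtis
   dissimilarity BC(x, y) = Σ|xᵢ − yᵢ| / Σ(xᵢ + yᵢ) of CAZyme
   compositions, per-genus section summaries with Kruskal–Wallis tests,
   and HMW/LMW (endo/exo) weight-class gene counts.
4. **Co-abundance groups.** Pairwise Pearson correlation of MAG relative
   abundances (p from t = r√((n−2)/(1−r²))), average-linkage clustering on
   1 − r with significant-edge components, section IV→V log10 fold
   changes, and per-group enzyme enrichment panels.
5. **Expression summaries.** Relative transcript expression of CAZymes,
   sulfatases and CGC-member CAZymes per gut section and taxon class, and
   selection of the clusters comprising the upper quarter of CGC
   expression.
6. **Synthetic communities.** A generator that plants taxon-class
   substrate guilds, CGCs with transporters/regulators, annotator
   disagreement noise, blocked co-abundance structure across gut sections
   and negative-binomial transcript counts — with full ground truth, so
   every stage above is validated end to end.

## Worked example

```r
library(cazyprofiler)

plan <- community_plan(rng_seed = 1)   # default 68-MAG community
plan
#> <community_plan> 68 MAGs (Bacteroidia=31, Clostridia=23, Bacilli=5,
#>   Gammaproteobacteria=4, Verrucomicrobiae=2, Cyanobacteriia=1,
#>   Spirochaetia=1, Desulfobacteria=1), 2000 genes/MAG, seed 1

generate_community(plan, "demo")
res <- run_pipeline(pipeline_config(), "demo", "demo_out")

res$cgcs
#> <cgc_set> 219 clusters over 652 member genes
#>   degradative: 108; substrate-assigned: 108
head(subset(res$cgcs$clusters, substrates != "")[
  , c("cgc_id", "mag_id", "n_degradative", "substrates", "evidence")])
#>       cgc_id  mag_id n_degradative  substrates              evidence
#> 2  CGC_00002 MAG_001             2 carrageenan carrageenan:dedicated
#> 5  CGC_00005 MAG_002             2        FCSP        FCSP:dedicated
#> 6  CGC_00006 MAG_002             2    alginate    alginate:dedicated

cmp <- compare_density_classes(res$profiles, "Bacteroidia", "Clostridia")
sprintf("W = %.0f, p = %.3g", cmp$statistic, cmp$p_value)
#> "W = 711, p = 5.73e-10"

res$weight_classes
#>   weight_class n_genes n_mags
#> 1          HMW    1443     67
#> 2          LMW    1652     64
```

The 219 clusters split into 108 degradative ones (all substrate-assigned
here because the generator plants clean clusters); the Wilcoxon test shows
the planted Bacteroidia CAZyme-density excess (median 33.5 vs 17.0 per
1000 genes); and exo-acting (LMW) genes outnumber endo-acting (HMW) ones
while being spread over fewer MAGs per gene, as expected for communities
where a few members initiate depolymerization and many consume the
released oligomers.

`demo_out/` holds every table as TSV (consensus calls, capability matrix,
CGCs, profiles, Bray–Curtis matrix, correlations, co-abundant groups, fold
changes, pooled enzyme counts, expression summaries) plus a run log.
Re-running on the same inputs is byte-identical.

A thin command-line wrapper is available at
`inst/scripts/cazyprofiler.R` (`generate` and `all` subcommands).

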