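# ssp — successor sequence prediction from ancestral protein lineages

`ssp` proposes candidate "next" amino-acid substitutions for a target
protein by extrapolating the physicochemical trends visible in its
reconstructed evolutionary history. It is aimed at protein engineers and
molecular evolution researchers who already run an ancestral sequence
reconstruction (ASR) pipeline and want to turn its output — rooted trees
with reconstructed node sequences — into a ranked, tiered list of
substitutions that continue the lineage's historical drift (towards, e.g.,
higher thermostability, activity, or solubility when that is what selection
has been pushing).

## The method

For each tree, the *main path* root → target is extracted. Every alignment
column read along that path is a residue **trajectory**; consecutive
identical residues collapse into groups, and boundaries between groups are
transitions. Each trajectory is projected through nine curated AAindex
descriptor scales (molecular weight, melting point, residue volume,
hydrophobicity, flexibility, transfer free energy, electrical effect,
polarity, isoelectric point). Per (site, scale), a weighted least-squares
line

&nbsp;&nbsp;&nbsp;&nbsp; y&#305; = β₀ + β₁·x&#305;,&nbsp;&nbsp;
w&#305; = 1 + d&#305;/d_max

is fitted (x = cumulative branch-length distance of the group, y = scale
value of its residue, recency-weighted), and evaluated one mean branch
length beyond the target: ŷ = β₀ + β₁·(x_last + step). The value ŷ is
inverted to the nearest residue on the scale — the predicted successor.
Sites with fewer than three transitions are excluded. Each prediction is
scored by **sequentiality** (% of transitions consistent with the trend
sign, out of 100), **fluctuation** (distinct residues ÷ groups), and a
**break-trend** flag (most recent transition opposing the trend), then
ranked, averaged across trees, and bundled: mutations supported by ≥ 2
scales are MAPs (mutation agreeing predictions), conflicting single-scale
residues at one site are SAPs (site agreeing), lone ones plain Predictions.

Dataset-preparation utilities (homolog identity/length filters, the
one-per-cluster sequence-file partitioning with a guaranteed target copy),
a seeded synthetic-history generator for testing, and the
mutational-enrichment statistic AAC (mean enrichment across conditions,
~1 for wild type) are included. Tree inference, alignment, and the ASR
itself are consumed as inputs, not recomputed.

## Worked example

```r
library(ssp)
tab <- load_default_indices()

# a synthetic 10-node lineage with two planted trends:
# rising molecular weight at site 4, falling hydrophobicity at site 9
h <- make_history(list(plant_spec(4, "FASG760101",  1L, 4L),
                       plant_spec(9, "WOLR790101", -1L, 3L)),
                  n_sites = 15, path_length = 10, seed = 21)

res <- ssp_predict(h$tree, h$sequences, "target", tab)
res
#> Successor predictions from 1 tree(s): 14 site/index/mutation records
#>   bundled: 2 MAP, 10 SAP, 0 Prediction

head(res$ranked[, c("rank", "position", "wild_type", "predicted",
                    "accession", "sequentiality", "fluctuation")], 3)
#>   rank position wild_type predicted  accession sequentiality fluctuation
#> 1    1        4         H         R FASG760101           100           1
#> 2    2        9         K         P FASG760102           100           1
#> 3    3        9         K         H WOLR790101           100           1

res$bundled[res$bundled$tier == "MAP",
            c("mutation", "tier", "n_support", "categories", "sequentiality")]
#>   mutation tier n_support          categories sequentiality
#> 1      H4R  MAP         2       Size;Polarity      87.50000
#> 2      K9H  MAP         2 Size;Hydrophobicity      83.33333
```

Both planted sites are recovered: the rising molecular-weight site 4 (wild
type H, 155 Da) is predicted to continue towards the heavier R (174 Da)
with a perfect sequentiality of 100 on the planted scale, and the
predictions agreeing across two scales surface as MAP-tier mutations H4R
and K9H. Background (constant) columns yield no predictions at all. On real
data the inputs are instead `read_newick()` trees and `read_fasta()`
alignments from your ASR pipeline, one pair per sequence file, and
`write_ssp_report()` dumps TSV/JSON reports. A command-line front-end
(`inst/scripts/ssp.R`, subcommands `indices`, `fixtures`, `predict`,
`prep`, `eval-aac`, `overlap`) wraps the same functions.

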