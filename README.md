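# mqtlkit

Meta-QTL analysis and candidate-gene screening for complex traits, built
for the drought-tolerance use case in rice but applicable to any
multi-study QTL compendium.

## The problem

Individual QTL mapping studies report loci with wide, unstable confidence
intervals that shift with genetic background and environment. Meta-QTL
analysis pools the QTLs of many independent studies on a common genetic
map and condenses co-locating loci into consensus **meta-QTLs (MQTLs)**
with sharply narrowed intervals, which can then be cross-validated
against GWAS hits and mined for candidate genes. `mqtlkit` implements
that whole chain as tested, scriptable R functions:

1. **CI standardization.** Each QTL's 95% CI width is derived from its
   population size *N* and phenotypic variance explained *R²* with the
   population-specific formulas
   CI = 530/(N·R²) (F2/F2:3/BC), CI = 163/(N·R²) (RIL/BIL) and
   CI = 97.462/(N·R²)^0.835 (DH).
2. **Consensus map and projection.** Per-study linkage maps are merged
   (robust rescaled-mean consensus with majority-order conflict
   resolution) and QTL peaks and intervals are projected by linear
   interpolation between shared flanking markers.
3. **Mixture meta-analysis.** On each chromosome the projected peaks
   *x\_i* with known positional standard deviations *s\_i = CI/3.92* are
   modeled as a K-component Gaussian mixture,
   ln L = Σ\_i ln Σ\_k π\_k φ(x\_i; μ\_k, s\_i²),
   fitted by EM; K is chosen by majority vote over **AIC, AICc, AIC3,
   BIC and AWE** (a model wins with ≥3 of the 5 minima). A QTL joins an
   MQTL only if its membership probability exceeds 60% *and* its peak
   lies inside the MQTL's pooled 95% CI. A 0.5 cM QTL-overview index
   profiles occurrence probability along the chromosome.
4. **GWAS validation.** MQTL peaks are anchored to physical coordinates
   and windows of peak ± 0.5 Mbp are intersected with marker–trait
   associations at −log₁₀(p) ≥ 5.
5. **Candidate funnel.** Genes inside MQTL windows are intersected with
   DEGs (|log₂FC| ≥ 1, FDR < 0.05), clustered by fuzzy c-means on
   two-genotype expression time courses, filtered to the
   mutant-up/wild-type-down signature cluster, and screened for the ABRE
   promoter element to yield differentially expressed candidate genes
   (DECGs).

A synthetic-data generator produces every input (QTL compendium, study
maps, marker anchors, GWAS panels, genome FASTA, GFF3 gene models, DE
statistics, expression time courses) with planted ground truth, so the
full pipeline runs and is testable offline.

## Worked example

Run the whole pipeline on a simulated bundle with two planted loci on a
40 cM chromosome, six planted candidate genes and four decoy classes:

```r
library(mqtlkit)
config <- list(
  simulation = list(seed = 42, n_chromosomes = 1, chrom_len_cm = 40,
                    true_mqtls = data.frame(chr = 1, cm = c(10, 25)),
                    qtls_per_locus = c(8, 12), mta_planted_fraction = 1,
                    n_candidates = 6, decoys_per_class = 3,
                    n_background_genes = 6, expression_noise_sd = 0.3),
  params = list(seed = 42, n_clusters = 4))
res <- run_pipeline(config, out_dir = "mqtl_run")
print(res)
#> meta-QTL pipeline run
#>   QTLs in/projected: 20 / 20
#>   MQTLs: 2 (mean CI 1.51 cM vs input 4.56 cM, 66.8% reduction)
#>   validated by MTAs: 2 (100.0%)
#>   genes in windows: 15; DEGs: 15; intersection: 12
#>   signature cluster: 4 (9 genes); DECGs: 6
res$mqtls[, c("mqtl_id", "peak_cm", "ci_low_cm", "ci_high_cm", "n_members")]
#>   mqtl_id  peak_cm ci_low_cm ci_high_cm n_members
#> 1 MQTL1.1 10.81294  10.09887   11.52701         5
#> 2 MQTL1.2 25.38339  24.58393   26.18286         5
```

The 20 simulated QTLs (planted at 10 and 25 cM) collapse into two MQTLs
whose peaks sit within 1 cM of the planted loci and whose mean CI is cut
from 4.56 to 1.51 cM; both MQTLs co-localize with planted GWAS SNPs, and
the candidate funnel returns exactly the six planted genes:

```r
res$decgs$gene_id
#> [1] "gene001" "gene002" "gene003" "gene004" "gene005" "gene006"
```

Every stage also writes TSV/JSON outputs (`mqtls.tsv`,
`model_selection.tsv`, `overview_index.tsv`, `mqtl_windows.tsv`,
`validation_summary.tsv`, `decgs.tsv`, `report.json`) under `out_dir`.

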