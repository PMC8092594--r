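# peakTargets

Identify candidate transcription-factor target genes from replicate ChIP-seq
peak calls — and validate every step against simulated data with known
ground truth.

Given scored peak calls (narrowPeak) for *k* treatment replicates of a
tagged factor and *m* untagged control replicates, plus a GFF3 gene
annotation, the package computes:

1. **Consensus binding regions** — maximal intervals covered by a peak with
   FDR < 0.001 (narrowPeak q-value > 3, strict) in *every* treatment
   replicate and overlapping (≥ 1 bp) *no* control peak passing the same
   cutoff.
2. **Target assignment** — a region (located by its centre) is assigned to a
   gene when the centre falls within 3 kb upstream to 1.5 kb downstream of
   the gene's coding span (strand-aware, boundaries inclusive) and no other
   gene's transcribed span lies between the centre and the coding span.
   Divergent promoters may receive two assignments.
3. **Positional enrichment** — observed promoter / transcribed / downstream
   fractions of region centres (relative to the transcript span) are
   compared with *B* = 10,000 bootstrap draws of equally many sites placed
   uniformly within the same target-gene windows; empirical p-values use the
   add-one rule `p = (r + 1)/(B + 1)`, plus a metagene histogram anchored at
   transcript start/end.
4. **Target-set overlap** — a two-tailed Fisher's exact test (probability-
   mass rule) of the overlap between the recovered target set and any
   reference gene list, over an explicit gene universe.

A seeded simulator (`simulate_genome()`, `simulate_peaksets()`,
`simulate_reference_set()`) generates annotations, replicate peak sets with
planted binding sites, background and control-artifact peaks, and reference
sets with controlled overlap, so precision/recall of the whole pipeline can
be measured exactly.

## Worked example

```r
library(peakTargets)

report <- run_pipeline(list(
  simulation = list(),          # default synthetic study:
                                # 300 genes, 60 true targets, 3+3 replicates
  seed = 17, B = 500,
  output_dir = "run17"
))
print(report)
#> pipeline run (seed 17)
#>   peaks_in               510
#>   peaks_passing_fdr      210
#>   consensus_regions      70
#>   regions_after_control  60
#>   assignments            60
#>   target_genes           60
#>   enrichment:
#>         zone observed_fraction null_mean    null_sd  p_enriched  p_depleted direction
#>     promoter        0.68333333 0.4541667 0.06499983 0.001996008 1.000000000  enriched
#>  transcribed        0.03333333 0.3172667 0.05733521 1.000000000 0.001996008  depleted
#>   downstream        0.28333333 0.2285667 0.05858735 0.219560878 0.860279441   neither
#>   overlap p = 1.57e-13 (40 shared)
#>   recovery: precision 1.000, recall 1.000
```

Reading the output: 510 simulated treatment peaks contain 210 confident
calls (60 true sites + 10 artifact sites per replicate); the three-way
intersection yields 70 consensus regions of which the 10 control artifacts
are excluded; all 60 true targets are recovered with no false genes.
Binding is significantly promoter-enriched and depleted in gene bodies
(empirical p at its floor `1/(B+1)` ≈ 0.002 with B = 500), and the
recovered set shares 40 genes with the simulated 80-gene reference list —
far above the ~16 expected by chance (Fisher p ≈ 2e-13).

The same pipeline runs on real files by replacing the `simulation` block
with `annotation`, `treatment_peaks`, `control_peaks` and optionally
`reference_set` paths; `inst/scripts/targetcall` wraps it for the shell
(`targetcall run --config run.yaml`).

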