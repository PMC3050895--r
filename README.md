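# activeflora

Analysis of the **active** human gut microbiota from community cDNA
(metatranscriptome) reads. Bulk RNA from a microbial community is mostly
ribosomal: the 16S transcript fraction reveals which bacterial families
are metabolically active, and the small non-ribosomal remainder reveals
what they are expressing. `activeflora` implements the full step-wise
analysis of such data as a reusable, tested R package:

* **Read triage** — length filter (≥ 60 bp), then homology against an SSU
  rRNA database at E ≤ 10⁻¹⁶, then LSU at E ≤ 10⁻⁴; the remainder is the
  putative-mRNA fraction. The thresholds come from a calibration sweep
  that minimizes cross-contamination between known SSU/LSU/mRNA fragment
  sets.
* **A self-contained search core** — ungapped seed-and-extend alignment
  (nucleotide, and six-frame translated vs protein) with exact gapless
  Karlin–Altschul statistics, `E = K·m·n·e^(−λS)`, λ solved from
  `Σ pᵢpⱼ e^(λsᵢⱼ) = 1`. No external aligner is needed.
* **Taxonomic classification** — word-based naive Bayes over 8-mers with
  bootstrap confidence (assignments truncated below confidence 0.5,
  deeper ranks reported `uc`), plus lowest-common-ancestor binning of
  protein hits; family × sample composition tables.
* **Diversity** — analytic rarefaction, Chao1 and ACE with standard
  errors, Shannon index (natural log), correspondence analysis
  (inertia = χ²/N).
* **Functional profiling** — protein-coding calls at E ≤ 10⁻³, COG
  assignment with the multi-COG (fusion/chimera) discard rule, per-sample
  category distributions, and rate-ratio enrichment
  `(n_c/n)/(N_c/N)` against the reference database; taxon × function
  matrix with hierarchical clustering; PWM-based small-RNA scan of the
  uncharacterized fraction; four-way accounting of the non-ribosomal
  reads against a contig catalogue.
* **A synthetic community generator** — taxonomy, divergent reference
  databases (with conserved SSU regions), Dirichlet family abundances and
  truth-labeled reads (~174 bp, mostly rRNA, with an injected COG
  category skew), so every stage is testable offline against known truth.

## Worked example

Simulate a three-sample community and run the whole pipeline:

```r
library(activeflora)
cfg <- run_config(spec = community_spec(n_samples = 3, reads_per_sample = 3000),
                  seed = 4)
bundle <- run_pipeline(cfg)
validate_bundle(bundle)
#> character(0)
bundle$table1
#>   sample SSU_prok SSU_euk  LSU non_rRNA total
#> 1    S01      491       0 2181      215  2887
#> 2    S02      493       0 2204      179  2876
#> 3    S03      516       0 2137      220  2873
```

The per-sample classes always sum to the total (the `character(0)` from
`validate_bundle` says every cross-table invariant holds). Diversity of
the active families per sample:

```r
bundle$diversity[, c("sample", "s_obs", "shannon", "chao1", "se_chao1")]
#>   sample s_obs  shannon chao1  se_chao1
#> 1    S01    14 1.965246 18.50 7.1937473
#> 2    S02    15 2.010272 15.25 0.7288690
#> 3    S03    14 2.175223 14.00 0.4818121
```

Shannon values near 2 with ~15 observed families are the regime typical
of healthy-gut family-level composition. Enrichment recovers the injected
expression skew — category G (carbohydrate metabolism) is simulated at
twice its database share and I (lipid metabolism) at half:

```r
subset(bundle$rate_ratios, category %in% c("G", "I"))
#>    category n_c   n N_c    N     ratio
#> 17        G  36 524  80 2000 1.7175573
#> 21        I   8 524  80 2000 0.3816794
```

(524 pooled assignments at this small scale; the ratio concentrates
around 2.0 and 0.5 as depth grows.) The accounting of the non-ribosomal
fraction against the synthetic contig catalogue:

```r
as.data.frame(bundle$accounting)
#>                   fraction count    percent
#> 1           protein_mapped   430 70.0325733
#> 2         protein_unmapped    94 15.3094463
#> 3   uncharacterized_mapped     4  0.6514658
#> 4 uncharacterized_unmapped    86 14.0065147
```

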