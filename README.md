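# delselect

Simulation and sequencing readout of DNA-encoded library (DEL) mock
selections.

## The problem

In a DEL catalyst selection, every small molecule in a combinatorial pool
is tethered to a DNA template that encodes its identity — here a 48 nt
template with two 18 nt primer sites flanking a 12 nt encoding region
(4^12 ≈ 16.8 million possible barcodes). A selection round applies a
functional pressure: members that catalyse bond formation to a
biotinylated reactant become biotinylated themselves and are captured on
streptavidin beads; everything else is washed away. The standard way to
validate such a platform is a **mock selection**: a known-active positive
control ("spike-in") is diluted hundreds- to thousands-fold into an
inactive library, one selection round is run, and the spike-in's **fold
enrichment** — post-selection frequency divided by pre-selection
frequency — is measured, either by a restriction digest (the spike-in
carries an EcoRV site in its encoding region) or by paired-end
sequencing of the pre- and post-selection pools.

`delselect` models this experiment end to end, for people designing or
analysing DEL selections: synthetic library construction with a diluted
spike-in, stochastic selection, Illumina-like paired-end read simulation,
read merging and barcode extraction, and per-barcode enrichment analysis.
It also processes user-supplied FASTQ and count tables with the same
machinery.

## The model

Survival of one selection round is Bernoulli per molecule with a
class-dependent probability: `p_cat` for the catalyst-bearing spike-in,
`p_bg` for inactive members (non-specific retention). For a spike-in at
pre-selection frequency `f0`, the expected post-selection frequency is

    f1 = f0 p_cat / (f0 p_cat + (1 - f0) p_bg)

and the expected fold enrichment depends only on `f0` and the survival
ratio `R = p_cat / p_bg`:

    E(f0, R) = R / (1 + f0 (R - 1))

`E` is strictly increasing in `R` and bounded by the **dilution ceiling**
`1/f0`: a 500-fold-diluted spike-in can be enriched at most 500-fold, a
2000-fold-diluted one at most 2000-fold. Sequencing at finite depth is a
multinomial draw from the (survival-reweighted) pool; reads acquire
i.i.d. per-base substitution errors and adapter read-through, are merged
by exhaustive-offset overlap consensus, and barcodes are re-extracted by
primer anchoring. Because an enrichment measurement constrains only `R`,
simulations are calibrated by inverting `E`: `R = 3000` gives an expected
1200-fold enrichment at 1/2000 dilution; `R = 124.75` and `R = 81.23`
give 100-fold and 70-fold at 1/500.

## Worked example

One mock selection at 1/2000 dilution with `R = 3000`, scaled to 20,000
background barcodes and 200,000 reads per sample:

```r
library(delselect)

run <- run_mock_selection(list(
  library   = list(n_background = 2e4, dilution = 2000),
  selection = list(p_cat = 0.30, p_bg = 1e-4,
                   depth_pre = 2e5, depth_post = 2e5),
  analysis  = list(pseudocount = 0),
  seed      = 101))
print(run)
#> Mock selection run (seed 101)
#>   library: 20001 members, dilution 1/2000
#>   selection: p_cat = 0.3, p_bg = 1e-04
#>   pre sample: 200,000 pairs, 200,000 merged, 199,950 barcodes extracted
#>   post sample: 200,000 pairs, 200,000 merged, 199,953 barcodes extracted
#> Mock-selection enrichment report
#>   barcodes analysed:    23323
#>   spike-in enrichment: 1234.99-fold (95% CI 1011.1-1508.5), rank 971
#>   vs nominal dilution: 1185.89-fold
#>   digest fraction:      pre 0.002446 -> post 0.597  (in-silico gel)
```

Reading the output: nearly every simulated pair merges and yields a
barcode (the few hundredths of a percent lost are pairs whose errors hit
the same primer twice); the
spike-in's measured enrichment, 1235-fold, sits within sampling error of
the expected `E(1/2000, 3000) = 1200.24` — at this depth the spike-in's
~100 pre-selection reads carry ~10% binomial noise, which the 95% CI
reflects, and the deeper default (`1e6` reads) tightens it to a few
percent. "vs nominal" recomputes enrichment against the nominal 1/2000
dilution instead of the sequenced pre-library. The digest fraction is the
in-silico gel: 60% of post-selection molecules carry the EcoRV site,
i.e. the spike-in now dominates the pool. The rank is computed at
pseudocount 0, where barcodes unobserved pre-selection have infinite
enrichment and are flagged (`present_pre = FALSE`) rather than dropped.

Closed forms are available directly:

```r
expected_enrichment(1 / 2000, 3000)   # 1200.24
calibrate_survival_ratio(1 / 500, 100)  # 124.75
```

Set `config$io$outdir` to write every intermediate artifact (library TSV,
paired FASTQ, count tables, enrichment TSV with CIs, summary JSON);
`inst/cli/delselect.R` wraps the same functions for shell use.

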