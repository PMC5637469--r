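---
title: "Modelling DEL mock selections: survival, sequencing, and enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DEL mock selections: survival, sequencing, and enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delselect)
```

## The experiment being modelled

A DNA-encoded library (DEL) couples each member of a combinatorial
small-molecule pool to a DNA template identifying it. In a catalyst
selection, members that catalyse bond formation to a biotinylated
reactant become biotinylated and are captured on streptavidin beads;
survivors are amplified and identified by sequencing. The platform's
validation experiment is a *mock selection*: a known-active positive
control is diluted into an inactive pool (500-fold for the gel-read
experiments, 2000-fold for the sequencing experiment), one round of
selection is run, and the positive control's fold enrichment is
measured. `delselect` reproduces that experiment in silico, stage by
stage, so that the arithmetic connecting survival probabilities,
dilution, sequencing depth and measured enrichment can be examined and
tested.

The template architecture is `primer5 (18 nt) + N12 (12 nt) + primer3
(18 nt)` = 48 nt; a 12 nt encoding region addresses $4^{12} \approx
16.8$ million molecules. The positive control's barcode carries an EcoRV
recognition site (`GATATC`), which supports a second, gel-based readout:
the fraction of post-selection molecules cut by EcoRV tracks the
positive control's frequency.

## The two-class survival model

Selection is modelled as independent Bernoulli survival with a
class-dependent probability: $p_{cat}$ for the catalyst-bearing
spike-in, $p_{bg}$ for every inactive member (non-specific retention,
background biotinylation, bead carry-over pooled into one number). For a
spike-in at pre-selection frequency $f_0$, the expected frequency among
survivors is

$$f_1 = \frac{f_0\,p_{cat}}{f_0\,p_{cat} + (1 - f_0)\,p_{bg}},$$

and the expected fold enrichment $E = f_1/f_0$ collapses to a function
of the survival ratio $R = p_{cat}/p_{bg}$ alone:

$$E(f_0, R) = \frac{R}{1 + f_0 (R - 1)} \;\le\; \frac{1}{f_0}.$$

Two structural facts follow and are enforced by tests. First, $E$ is
strictly increasing in $R$ with $E(f_0, 1) = 1$. Second, the *dilution
ceiling*: no measurement can exceed $1/f_0$, so a 500-fold dilution caps
at 500-fold and a 2000-fold dilution at 2000-fold. This is why the
sequencing experiment, designed to resolve enrichments around a
thousand-fold, uses the deeper 1/2000 dilution.

An enrichment measurement therefore constrains only $R$, never
$p_{cat}$ and $p_{bg}$ separately. `calibrate_survival_ratio()` inverts
$E$; the package's reference calibrations are $R = 3000$ (expected
1200.24-fold at $f_0 = 1/2000$), $R = 124.75$ (100-fold at $1/500$) and
$R = 81.23$ (70-fold at $1/500$). The default absolute scale,
$p_{cat} = 0.30$ with $p_{bg} = 10^{-4}$, is a plausible capture
efficiency for a single-round bead pull-down; any pair with the same
ratio gives the same expected enrichment, and only the ratio is tested.

```{r closed-forms}
expected_enrichment(1 / 2000, 3000)
expected_enrichment(1 / 500, 124.75)
calibrate_survival_ratio(1 / 2000, 1200)
```

## What the synthetic-data generator emulates

`generate_library()` draws distinct background barcodes uniformly from
the $4^{12}$ space (exact index sampling without replacement up to
15 nt barcodes) and `spike_in()` adds the positive control at
$f_0 = 1/\text{dilution}$, rescaling the background. The default
background of $10^5$ distinct barcodes, rather than the full 16.7
million of the experiment, keeps one run in desk-scale memory; because
survival depends only on class, the spike-in's enrichment distribution
is unchanged by the background's granularity (`aggregate_library()`
takes this to the extreme of one pooled background row, and a test
checks the equivalence). Sequencing depth enters as a multinomial draw
of `depth` reads from the pool frequencies — pre-selection from the
library, post-selection from the survival-reweighted frequencies.

The read simulator emulates a MiSeq-like run: 2×75 nt paired reads from
the 48 nt insert, so both mates read through into adapter on the far
side; i.i.d. per-base substitution errors (default rate 0.001, the
right order for a quality-filtered Illumina run); constant Phred
quality (default Q30). Read length, adapters, quality and error rate
are configurable because none of them is public for the original
experiment. The generator does **not** model indels, quality decay
along the read, PCR amplification bias (exposed as an option, default
off, so no unmodelled variance enters the calibrated comparisons),
chimeras, or index hopping. Passing tests therefore demonstrate the
pipeline's arithmetic and robustness to substitution noise, not
robustness to every artefact of real sequencing data.

## Read merging and barcode extraction

`merge_pair()` reverse-complements read 2 and scans *every* relative
offset against read 1, including negative offsets where the insert is
shorter than the read (the 48 nt regime). Among offsets with overlap
$\ge$ `min_overlap` (default 10 nt) and mismatch fraction $\le$
`max_mismatch_frac` (default 0.25), the most matching bases win; ties
prefer fewer mismatches, then the smaller insert. If no offset
qualifies, the pair is reported as `too_many_mismatches` when the best
offset still aligns at least `min_overlap` bases, `no_overlap`
otherwise — so unrelated reads and noisy-but-related reads are
distinguishable in the accounting. Exhaustive scanning is exact for
short inserts and doubles as its own specification; the hot loop is a
small C++ kernel (word-wise byte comparison with offset pruning), and
an independent plain-R reference implementation in the test helpers
checks it case by case. Consensus takes the higher-quality base at each
disagreement, ties to read 1 — with the default constant-quality model
this means read-1 errors survive merging in the overlap, which is why
the round-trip tests also exercise heterogeneous qualities.

`extract_barcode()` anchors on the primers: leftmost match of `primer5`
with at most `max_primer_mismatch` substitutions (default 1; no
indels), then leftmost match of `primer3` downstream. The enclosed
region is accepted only at exactly 12 nt; everything else is rejected
with a reason code, never silently truncated. Errors inside the
encoding region pass through and create low-count satellite barcodes —
deliberately, since the original analysis describes no error
correction; an optional Hamming-1 collapse (`collapse_hamming1()`) is
provided but off by default. Satellite formation deflates pre- and
post-frequencies by the same factor, so spike-in enrichment is
unbiased by it.

## Enrichment arithmetic

`fold_enrichment()` computes frequency-ratio enrichment with pseudocount
$\alpha$ over the $K$ barcodes in the union of both tables:
$\hat E_i = \frac{(b_i + \alpha)/(n_2 + \alpha K)}{(a_i + \alpha)/(n_1 +
\alpha K)}$. $\alpha = 0$ (the pipeline default) gives exact ratios and
two exact invariants used as tests: $\sum_i \hat f_{pre,i}\hat E_i = 1$
and $\hat E_i \le 1/\hat f_{pre,i}$. $\alpha = 0.5$ (Haldane–Anscombe)
keeps barcodes with zero pre-counts finite; they are flagged
(`present_pre = FALSE`) rather than dropped. The 95% CI is the normal
approximation on $\log \hat E$ with variance $1/a - 1/n_1 + 1/b - 1/n_2$
on smoothed counts — adequate away from zero counts, which is what the
pseudocount provides. Whether the experiment's printed enrichment was
computed against the sequenced naive library or the nominal dilution is
not stated, so the summary reports both (`spike_enrichment` vs
`spike_enrichment_vs_nominal`).

`digest_fraction()` is the in-silico gel: the count-weighted fraction of
templates containing the digest site, scanning the full 48 nt template
so that background barcodes that spuriously contain or create the site
(expected at a rate of about $7 \times 4^{-6}$ per 12 nt barcode) are
counted, exactly as a real digest would cut them.

## Numerical and design choices

* **Seeding.** One master seed per run; each stage (library, selection,
  pre-reads, post-reads) consumes an independent child seed drawn from
  it. Reruns are bit-identical, and seeds are recorded in the report
  metadata.
* **Collapsed read storage.** Identical read pairs share one row with a
  multiplicity, so a depth-$10^6$ sample stores ~2×10^5 distinct pairs
  instead of 10^6; FASTQ export expands to one record per molecule.
  This is a storage choice only — counting is molecule-weighted
  everywhere.
* **Primer/adapter defaults.** The experiment's primers and adapters are
  not public; defaults are fixed GC-balanced 18-mers and TruSeq-style
  stubs, used consistently and overridable in the config.
* **Degenerate inputs.** Zero-length barcodes are allowed in the
  architecture (template = primers only); empty libraries, all-zero
  survival, and zero-total count tables raise immediately with the
  offending stage named.
* **Problem sizes.** The validation suite runs the full pipeline at
  depth $10^6$ per sample over five seeds per calibration, which holds
  the spike-in's sampling error near 2% — comfortably inside the 5%
  band used to compare against the reference enrichments; smaller
  property tests use depths of $10^4$–$10^7$ where the binomial error
  budget, not realism, dictates the size.

## Known limitations

The survival model treats members independently: inter-strand effects
(an active member biotinylating a neighbour) are representable only as
part of $p_{bg}$. Multi-round selection chaining is possible by feeding
a run's post-selection table back in, but is untested against any
reference. The error model is substitution-only, and primer matching
tolerates substitutions but not indels — an indel in a primer loses the
read, which mirrors common amplicon pipelines but underestimates
recovery from indel-rich platforms. Enrichment CIs ignore
overdispersion from PCR; with amplification bias enabled they are
anticonservative.
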