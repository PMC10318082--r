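---
title: "Methods: simulating and decoding plate-based optogenetic DNA image storage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding plate-based optogenetic DNA image storage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baccam)
```

## The recording channel

The system this package models stores a binary 8×12 image in DNA without
synthesising any new sequence. Each well of a 96-well plate holds
*E. coli* carrying a light-activated Cre recombinase and a recording
plasmid with two directly repeated 34-bp LoxP sites around a terminator
region. Light exposure activates Cre, which excises the inter-LoxP
segment, leaving a single LoxP junction. A well therefore encodes one bit
in the *composition* of its plasmid population: mostly-excised ⇒ the well
saw light (bit 1), mostly-intact ⇒ it did not (bit 0).

Spatial identity is preserved by two barcode layers appended by PCR:

* a **well-code** — a unique oligonucleotide per well, mapping each read
  back to a pixel;
* a **dual index pair** (i7, i5) — one pair per image, so several plates
  can be pooled in one tube and demultiplexed from one sequencing run.

After pooling, sequencing returns reads of the form

```
[i7][pad][well-code][spacer, red channel only][left flank][LoxP]([intervening][LoxP])[right flank][i5]
```

where the parenthesised part is present only on intact templates. The
decoder recovers, for every well and colour channel, the counts of
excised and intact reads, and summarises them as the bounded excision
fraction

$$ v_w \;=\; \frac{n^{\text{excised}}_w}{n^{\text{excised}}_w + n^{\text{intact}}_w} \in [0,1]. $$

We use this bounded fraction rather than the raw excised:intact quotient:
the two are monotone-equivalent for thresholding, but the fraction is
defined when a well has no intact reads and lives on a fixed [0, 1] axis
that the clustering settings (DBSCAN's `eps`, the ON/OFF cutoff) can
refer to.

## The synthetic channel

`simulate_plate()` is a generative model of everything between the light
pattern and the FASTQ file:

| parameter | default | meaning |
|---|---|---|
| `f_on` | Beta(9, 1) | latent excision fraction of a light-exposed well (mean 0.9) |
| `f_off` | Beta(1, 9) | latent excision fraction of an unexposed well (mean 0.1) |
| `depth_mean` | 500 reads/well | mean per-well coverage |
| `depth_dispersion` | 5 | negative-binomial size (well-to-well coverage variation); `Inf` = fixed depth |
| `sub_error_rate` | 0.001 /base | i.i.d. substitution errors |

Each well draws its latent fraction $f_w$ from the Beta matching its true
bit, a read count $n_w$ from the negative binomial, and then each read is
excised with probability $f_w$; sequences are assembled from the template
segments and corrupted with substitutions. The Beta/negative-binomial
forms are modelling choices: the biology constrains only that the ON and
OFF fraction distributions be separated, and overdispersed per-well
coverage is the norm for barcoded amplicon pools. A scalar `f_on = 1,
f_off = 0` with fixed depth gives the *noiseless channel*, for which
decoding must be exact — the pipeline's basic identity.

What the generator deliberately does **not** emulate: PCR chimeras, index
hopping, polymerase-specific error spectra, quality-score variation
(qualities are constant Q30 placeholders), and recorder growth dynamics.
Passing tests therefore certify the computational pipeline against this
idealised channel, not against every artefact of a real sequencing run.

Library operations are modelled explicitly because they are what the
storage claims rest on: `pool_images()` concatenates and shuffles indexed
read sets; `dilute(pool, f)` keeps each read with probability $1/f$
(binomial thinning, the in-silico tenfold serial dilution);
`random_access()` resamples reads matching one index pair to
`amplification`× their count while off-target reads survive only at
`off_target_rate`, emulating index-selective re-amplification.

For the random-access experiment we simulate 5000 reads/well before
dilution, so that a 1000× dilution leaves ≈5 reads per well — the regime
in which individual barcodes "number in the low single digits" and some
wells drop out entirely, which is exactly where selective re-amplification
earns its keep.

## Decoding

`demultiplex()` assigns a read to an image only when **both** indexes
match a table entry within `max_mismatch` (default 1); ties are
discarded, never broken arbitrarily, because a silently mis-assigned read
corrupts a pixel. The same rule governs well-code matching
(`match_barcode()`), whose code sets are generated by greedy closure with
pairwise Hamming distance ≥ 3 — enough to correct any single
substitution (sphere packing: $d_{\min} \ge 2k+1$ corrects $k$ errors).

Read classification uses fixed-offset signature windows instead of
alignment: after the left flank and first LoxP site, an intact read
continues into the intervening region, an excised read continues straight
into the right flank. A window (16 bp, ≤2 mismatches) against each
reference decides EXCISED / INTACT; a read matching neither or both is
AMBIGUOUS and is counted but never enters a ratio. These are structured
amplicons with no indels in the model, so positional anchoring suffices;
it is also what keeps the decoder fast enough to process millions of
reads in seconds.

Wells with zero informative coverage are reported **MISSING**, not 0.
They are excluded from clustering and only at the very end imputed as
state 0 — "no reads, no evidence of exposure" — with a warning. One
consequence: a plate whose observed wells are all ON but which has
missing wells decodes with mode `ALL_ON` yet zeros at the missing
pixels; the mode describes the observed wells.

## The automated deconvolution workflow

`deconvolute()` composes four stages; the design follows the automated
image-reconstruction workflow of the recording platform's original
description, with each stage implemented from first principles:

1. **Outlier curation.** Local Outlier Factor on the 96 ratio values
   (`n_neighbors` 20 for blue-channel data, 10 for red). LOF is computed
   from its definition (k-distance, reachability distance, local
   reachability density, LOF = mean neighbour-LRD over own LRD). A well
   is an outlier iff its score exceeds both the `1 − contamination`
   score quantile (default contamination 0.05) *and* an absolute floor
   of 1.5. The quantile caps how many wells can ever be flagged; the
   floor — the conventional "clearly less dense than its neighbours"
   level — guarantees that clean, evenly dense plates flag nothing,
   which a pure quantile rule cannot (it always flags its top 5%).
   Flagged wells are moved to the nearest inlier value (ties to the
   lower value); the operation is idempotent.

2. **1-D clustering.** The menu is k-means (`stats::kmeans`, 25 seeded
   restarts), DBSCAN, OPTICS with steep-area (ξ) extraction, and a
   Gaussian mixture fitted by EM (k-means++-style init, log-likelihood
   tolerance 1e-6, ≤500 iterations, variance floor 1e-6). DBSCAN/OPTICS
   noise points are attached to the nearest cluster by value before
   grouping; a density method that finds no cluster at all falls back to
   a single cluster with a warning. When the data holds fewer distinct
   values than requested clusters (the noiseless channel produces
   exactly {0, 1}), the cluster count is reduced to the number of
   distinct values rather than erroring — a 3-component request on a
   two-valued plate must still decode it.

3. **Full ON/OFF assessment.** With cluster means sorted ascending, the
   plate is `ALL_ON` if even the lowest mean exceeds the cutoff,
   `ALL_OFF` if even the highest is below it, else `MIXED`. The default
   cutoff is 0.5 on the bounded fraction — the symmetric point of the
   [0, 1] axis; `calibrate_cutoff()` instead derives it from a
   collection of fitted plates as the midpoint between the grand means
   of the lowest and highest clusters.

4. **Cluster grouping.** In MIXED mode, blue-channel plates map the
   lowest-mean cluster to OFF and every other cluster to ON; red-channel
   plates map the *two* lowest-mean clusters to OFF (their raw ratio
   distributions run higher), with the obvious reduction when only two
   clusters exist.

`oracle_threshold()` implements the with-foreknowledge benchmark: an
exhaustive scan over all midpoints between adjacent sorted values,
returning the accuracy-maximising threshold (ties to the lowest). It is
used only to benchmark the automated workflow, since it requires the
encoded image.

## Choice of defaults, and a shallow-coverage caveat

The package default is the **2-component GMM** (and k-means k = 2): the
channel is binary, and the platform's own production decode defined its
threshold between two GMM clusters. A 3-component fit is valuable when a
genuine intermediate-excision population exists, but under the symmetric
Beta noise model above, the third component simply splits whichever Beta
cloud holds more wells, and the grouping rules then mislabel that
sub-cluster — on mixed patterns this costs tens of pixels. The
3-component GMM, both k-means settings, both DBSCAN radii and OPTICS all
remain available and all decode the noiseless channel perfectly.

Two further numerical caveats, both visible in the test suite:

* **OPTICS ξ fragmentation.** On continuous noisy ratios the ξ method
  (ξ = 0.05, `min_samples` 5) extracts many small leaf clusters — steepness
  is relative, so tiny reachability fluctuations inside a dense cloud
  qualify as steep at small scales. This matches the reference behaviour
  of the standard implementations; it makes OPTICS a poor default for
  noisy plates even though it is exact on well-separated ones.

* **The zero atom under shallow coverage.** Dilution to a few reads per
  well quantises the ratios and places a point mass at exactly 0. The
  maximum-likelihood 2-component Gaussian fit of such data is a
  variance-floor spike on the zeros plus one broad catch-all component —
  an EM fixed point from any initialisation, not a bug — whose top mean
  can fall below the cutoff and flip the plate to `ALL_OFF`. The
  dilution and random-access analyses therefore use the k-means branch
  of the menu, which has no density term and keeps the semantic
  low/high split in this regime. This is the package's standing
  recommendation for coverage below roughly 10 reads per well.

## Problem sizes and reproducibility

The shipped analyses use 96-well plates at depth 500 (≈48,000 reads per
plate) with 20 seeded replicates for the stochastic summaries, a
five-image pool at depth 5000 (≈2.4 million reads) for random access, and
100 seeded runs for GMM parameter recovery. Every randomised operation
takes an explicit seed; pipeline stages derive their seeds from one
master seed by a stable hash of the stage name (`stage_seed()`), so any
stage can be reproduced in isolation and an end-to-end run is a pure
function of the master seed. Identical configuration and seed give
byte-identical decode reports.

```{r example, eval = FALSE}
codes <- generate_well_codes(96, seed = 1)
truth <- pattern_grid("SMILEY")
reads <- simulate_plate(truth, channel_params(), codes,
                        default_index_table()[1, ], seed = 7)
ratios <- count_and_ratio(reads, codes)
dec <- deconvolute(ratios, truth = truth, seed = 7)
print(dec)
plot(dec)
```

## Known limitations

* The quality channel is ignored end to end (constant placeholders), so
  quality-aware filtering cannot be studied with this simulator.
* Indels are outside the error model; the fixed-offset signature windows
  would mis-window a read with an indel upstream of the locus.
* The red-channel grouping rule ("two lowest clusters are OFF") is
  implemented verbatim from its source description; the distributional
  asymmetry motivating it is not quantified there, so the rule is applied
  as stated rather than re-derived.
* Accuracy figures quoted anywhere in this package are computed by the
  test suite or the acceptance script on the synthetic channel; they are
  not measurements of the original wet-lab datasets.
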