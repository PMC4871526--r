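# apseg — attraction propagation for seeded polyp segmentation

`apseg` segments a polyp-like object in an endoscopic image from a single
foreground seed plus an automatically placed frame of background seeds (the
"viewfinder"). It is aimed at computer-aided diagnosis pipelines for optical
colonoscopy, where asking the clinician for one click — or none, when the
polyp sits in a fixed position of the frame — is the only acceptable amount
of interaction.

## The model

The image is a weighted graph on the pixel lattice with edge weights

    w_ij = exp(-beta * |g_i - g_j|) + epsilon_w

for normalized intensities g in [0, 1]. The classical random walker (RW)
computes, for each label c in {f, b}, transition probabilities x^c by
minimizing the smoothness energy sum_ij w_ij (x_i^c - x_j^c)^2 with seeds
fixed, i.e. by solving L_U x^c = -B^T m^c on the unseeded nodes. With sparse
seeds the probabilities fail to propagate far from the single foreground
seed — the *small cut* problem.

Attraction propagation (AP) adds a shape-driven attraction term
sum_{i in A} D(a_i, x_i^c, tau_i^c):

* **A**, the attraction region, is the thresholded support of a *shape
  probability matrix* SP(m, n) = Fr(m, n)/Ns learned from Ns
  centroid-calibrated ground-truth masks, translated so its center sits on
  the foreground seed. The threshold matrix is T = SP where SP >= Gamma.
* **tau**, the range base: tau^f equals the shifted threshold matrix inside
  A, tau^b = 1 - tau^f, both 0 outside.
* **a_i = exp(-|g_i - g_s|)**, the attraction factor, weighting each region
  pixel by its similarity to the seed intensity g_s.

Three distance forms D give three variants, each solved as two sparse
symmetric linear systems on the unseeded block:

| variant | D(a, x, tau)          | linear system                                   |
|---------|-----------------------|-------------------------------------------------|
| PEA     | a (x - tau)^2 / 2 tau | (L_U + A_U diag(1/tau^c)/2) x = -B^T m^c + a_U  |
| INN     | a x tau               | L_U x = -B^T m^c + A_U tau^c                    |
| L2      | a (x - tau)^2         | (L_U + A_U) x = -B^T m^c + A_U tau^c            |

A pixel is labeled foreground where x^f >= x^b. With an empty region (or no
prior) all variants reduce exactly to RW. Defaults follow the published
operating points: beta = 310, Gamma = 0.8 (PEA/L2); beta = 340, Gamma = 0.6
is the reported INN setting.

## Worked example

Everything below is synthetic, so it runs without any external database:

```r
library(apseg)

corpus <- generate_mask_corpus(50, rng_seed = 101)       # 50 training masks
prior  <- train_shape_prior(corpus, gamma = 0.8)          # SP + threshold

ph    <- generate_phantom(phantom_spec(gap_fraction = 0.3, rng_seed = 42))
seeds <- viewfinder_seeds(96, 96)                         # frame + center seed

seg_ap <- ap_segment(ph$image, seeds, prior, variant = "l2", beta = 310)
seg_rw <- ap_segment(ph$image, seeds, prior = NULL, variant = "rw")

for (s in list(seg_ap, seg_rw)) {
  r <- metric_report(confusion(s$mask, ph$mask))
  cat(sprintf("%-5s dice %.3f  aac %.3f  precision %.3f  f2 %.3f\n",
              s$variant, r$dice, r$aac, r$precision, r$f2))
}
```

Output:

```
l2    dice 0.968  aac 0.937  precision 1.000  f2 0.949
rw    dice 0.931  aac 0.870  precision 1.000  f2 0.893
```

The phantom has a 30% weak-boundary arc (its edge is feathered below the
noise level there). The L2 attraction variant recovers more of the object
(higher AAC/recall) than the plain random walker at identical precision; on
phantoms where RW's single seed loses the percolation race against the
background frame entirely, the gap is much larger (see the methods
vignette). AAC — annotated area covered — is the fraction of true object
pixels retrieved, identical to recall; F2 is the recall-weighted F-score.

## Command line

```sh
Rscript inst/cli/apseg.R simulate    --n 20 --out phantoms/ --seed 1
Rscript inst/cli/apseg.R train-prior --masks phantoms/ --gamma 0.8 --out prior.json
Rscript inst/cli/apseg.R segment     --image phantoms/image_001.png --prior prior.json \
                                     --variant l2 --beta 310 --gamma 0.8 --out mask.png
Rscript inst/cli/apseg.R evaluate    --pred preds/ --truth phantoms/ --out report.csv
```

All flags can come from `--config file.yaml|json`; a provenance JSON is
written beside every output, and identical configurations produce
bit-identical artifacts.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end behavior from scratch: it trains a shape
prior on a fresh 50-mask corpus, segments 20 clean and 20 weak-boundary
phantom sets with L2-AP, PEA-AP and RW, and prints the mean Dice per method
and setting before writing the JSON result file.
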