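# mavescore

Scoring and clinical calibration for TileSeq-based multiplexed assays of
variant effect (MAVEs), with the HMBS yeast-complementation screen as the
motivating design: two protein isoforms differing by a 17-residue N-terminal
truncation, two mutagenized regions sequenced as amplicon tiles, two
selection replicates, and a clinical endpoint — ACMG/AMP evidence strengths
for missense variants in acute intermittent porphyria.

## What it computes

Starting from per-tile, per-condition, per-replicate variant read counts
(plus matched wild-type-control counts), the package:

1. **Scores variants.** Frequencies (`count/depth`) are filtered against the
   wild-type-control background (retained when
   `freq ≥ wt_mean + 3·wt_sd`), wild-type frequencies are subtracted, and
   each variant gets an enrichment ratio
   `Φ = adjusted_select / adjusted_nonselect` and a functional impact score

   ```
   FS = ln(Φ / Φ_STOP) / ln(Φ_SYN / Φ_STOP)
   ```

   where `Φ_STOP` / `Φ_SYN` are the median nonsense / synonymous enrichment
   ratios per region (nonsense variants in the last 14 residues are excluded
   from the anchor). `FS = 0` is null-like, `FS = 1` wild-type-like.
   Standard errors combine between-replicate disagreement with a monotone
   trend of disagreement versus pre-selection frequency (empirical-Bayes
   shrinkage), and quality filters remove variants with `se > 0.3` or
   nonselect frequency below 0.005%.

2. **Assembles a combined map.** The erythroid map is mapped into
   ubiquitous coordinates (offset 17), affinely rescaled to minimize the
   mean squared score difference over shared variants, and combined with the
   ubiquitous map by inverse-variance weighting
   (`σ² = 1/(1/σ₁² + 1/σ₂²)`), with per-variant delta scores.

3. **Calibrates clinically.** Scores of labeled pathogenic/benign reference
   variants give balanced precision-recall curves (`BP = recall/(recall+FPR)`),
   AUBPRC and R90BP; Gaussian maximum-likelihood densities for the two sets
   give a log10 likelihood ratio of pathogenicity
   `LLRp(f) = log10[ρ(S|+)(f) / ρ(S|−)(f)]`; and a Tavtigian-style
   posterior-odds search calibrates ACMG/AMP evidence thresholds: evidence
   levels carry odds `X^(1/2^k)`, and the smallest very-strong odds `X`
   satisfying every combining rule's posterior constraint (>0.99 pathogenic,
   >0.90 likely pathogenic, <0.10 likely benign, <0.01 benign at prior 0.10)
   is located and rounded as in that framework.

4. **Simulates TileSeq data.** A generator with known ground-truth fitness
   (bimodal missense fitness, 2.5% hyper-complementing fraction, 1.7
   amino-acid changes per clone, log-normal library abundance, competitive
   selection `g(w) = exp(r(w−1))`, multinomial tile sequencing with a
   control-shared error floor) makes the full pipeline testable with no
   external downloads.

## Worked example

```r
library(mavescore)

cfg <- simulation_config(rng_seed = 42)      # 361 residues, 2x5 tiles, 2 reps
sim <- simulate_tileseq(cfg)
map <- score_tileseq(sim$counts, sim$controls,
                     scoring_config(protein_length = cfg$protein_length))
head(map[map$class == "missense", c("variant", "region", "phi", "score", "se", "pass")])
#>   variant region        phi       score         se pass
#> 3     M1A     R1 0.89027333  0.92678163 0.02849151 TRUE
#> 4     M1C     R1 0.04276749 -0.08048789 0.08247164 TRUE
#> 5     M1D     R1 0.81621326  0.89938830 0.01308546 TRUE

m <- merge(map[map$pass, ], sim$truth[, c("variant", "w")], by = "variant")
cor(m$score, m$w)
#> [1] 0.9733277
```

Scores near 0 (e.g. `M1C`, `Φ ≈ 0.04`) are variants depleted like nonsense
variants under selection; scores near 1 behave like synonymous variants.
The recovered scores correlate at r ≈ 0.97 with the generator's true
fitness values among quality-passing variants.

```r
calibrate_acmg_thresholds(prior = 0.10)
#> ACMG/AMP evidence thresholds (log10 likelihood ratio)
#>   prior P+ = 0.1; very-strong odds = 350 (raw 350.4666)
#>   PVSt  2.5441
#>   PSt   1.2720
#>   PM    0.6360
#>   PSu   0.3180
#>   BSu  -0.3180
#>   BSt  -1.2720
#>   binding rule: LP: 1 strong + 1 moderate
```

A variant with `LLRp = 0.70` therefore provides moderate evidence of
pathogenicity; `LLRp = −1.5` is strong evidence of benignity
(`assign_evidence()`).

The whole chain — simulate both isoforms, score, combine, evaluate, fit
densities, assign evidence — runs as one call:

```r
res <- run_pipeline(pipeline_config(), out_dir = "out")
res$evaluation$unmasked$r90bp   # recall at 90% balanced precision
```

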