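# metabarcode

Simulation and analysis of **pixelated high-Q metasurface biospectroscopy**
with explainable deep-learning classification, for spectroscopists and
methods developers working on surface-enhanced infrared absorption (SEIRA)
sensing of lipid membranes.

## The problem

A metasurface "barcode" of 49 metapixels — each a sub-array of silicon
resonators with one sharp quasi-BIC resonance — covers 1400–1800 cm⁻¹ with
linearly spaced resonance positions. A supported bilayer of the
photoswitchable lipid AzoPC (trans ⇌ cis under 465/365 nm light) sits on
the chip in D2O; its vibrational bands (CH₂ scissoring 1470 cm⁻¹,
azobenzene ring breathing 1496 cm⁻¹, cis-only N=N stretch 1511 cm⁻¹, ester
C=O 1735/1742 cm⁻¹) attenuate the resonances they overlap. Reading each
metapixel's attenuation at its own resonance yields a 7 × 7 absorbance
image — the molecular barcode — and a 1D CNN classifies the membrane
photostate from the metapixel spectra. Integrated gradients (IG) reveal
which metapixel drives the decision, and a small "pruned" CNN is trained
on that single metapixel.

The package provides, as tested R code:

* a **forward model**: temporal coupled-mode (Fano) resonances
  `R(ν) = B(ν)·|r_bg + a·γ_r / (i(ν−ν₀) + γ_r + γ_nr + ℓ(ν))|²` with
  `γ_r + γ_nr = ν₀/(2Q)`, Lorentzian molecular loss channels ℓ(ν), D2O
  Beer–Lambert attenuation B(ν), first-order photoswitching kinetics,
  additive noise and Ornstein–Uhlenbeck drift;
* **barcode layout**: pixel doubling, two extra metapixels, seeded random
  10 × 10 arrangement and its inverse mapping;
* **extraction**: block-mean spectra from hyperspectral cubes, duplicate
  averaging, absorbance `A = −log₁₀(R/R_D2O)` at resonance, third-order
  Savitzky–Golay spectrum reconstruction, 7 × 7 barcode maps, time-series
  absorbance with the 14-min/LED-on exclusion rules;
* **classifiers**: the original 6-conv-layer 1D CNN (128/100/80/60/40/20
  filters) and the pruned 4-layer CNN (8/16/32/32), trained 160 epochs
  with dropout 0.2 on a stratified 70/30 split; in-package
  single-precision conv/backprop/Adam, fully seeded;
* **attribution**: integrated gradients with zero baseline and
  midpoint Riemann sum, completeness residuals, per-metapixel importance,
  top-pixel selection, per-frame time-series classification.

## Worked example

```r
library(metabarcode)

cfg <- pipeline_config(seed = 1)   # study defaults: 494 spectra, 160 epochs
report <- run_full(cfg)

report$eval_original$accuracy      # 1  (validation accuracy, 6-layer CNN)
report$eval_pruned$accuracy        # 1  (4-layer CNN on the selected metapixel)
report$selected
#> $index
#> [1] 14
#> $nu0
#> [1] 1508.333
```

The selected metapixel resonates at 1508 cm⁻¹, next to the cis-only
1511 cm⁻¹ N=N stretch — the model finds the chemically informative pixel
on its own. `report$timeseries` holds the per-frame cis probability along
a 3-cycle UV/VIS switching protocol with exclusion flags; the predicted
state flips within two 64-s frames of each LED-off boundary.

Smaller pieces work standalone:

```r
g  <- spectral_grid()                        # 1300–1800 cm^-1, 251 samples
bc <- build_target_barcode()                 # 49 designs, 1400–1800 cm^-1
ly <- double_and_randomize(bc, seed = 0)     # 100 slots, seeded permutation
cube <- simulate_cube(ly, membrane_state(0.9), grid = g, seed = 1)
avg  <- average_doubled(extract_metapixel_spectra(cube, ly), ly)  # 49 spectra
```

A thin CLI wrapper lives at `inst/cli/metabarcode.R`
(`metabarcode.R run-full --seed 1 --out DIR`).

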