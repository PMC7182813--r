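# adhesim

Quantitative tools for studying **microbial adhesion to solid surfaces**
— including residual plastics considered as cheap immobilization supports
for whole-cell or cell-debris biocatalysts. The package serves
experimentalists who characterize substrata by sessile-drop contact
angles, score adhesion from optical micrographs, and assay the enzymatic
activity of debris immobilized on polymers.

Three analysis stages, each with a synthetic-data generator carrying
known ground truth so the whole pipeline is testable without external
data:

1. **Surface energetics.** The van Oss–Chaudhury–Good decomposition: for
   a solid *j* probed with liquid *i*,

   (1 + cos θᵢ) γᵢ = 2 ( √(γⱼᴸᵂ γᵢᴸᵂ) + √(γⱼ⁺ γᵢ⁻) + √(γⱼ⁻ γᵢ⁺) ),

   solved as a linear system in (√γⱼᴸᵂ, √γⱼ⁺, √γⱼ⁻) from three liquids
   (water, formamide, methylene iodide shipped as the default probe
   set), with γᴬᴮ = 2√(γ⁺γ⁻), γᵗᵒᵗ = γᴸᵂ + γᴬᴮ. Negative solved roots
   are squared-and-flagged, never zeroed; signed roots are retained so
   forward modeling reproduces the measured angles. Includes Rijnaarts
   hydrophobicity banding of the water angle, Monte-Carlo uncertainty
   propagation, a conditioning guard for degenerate liquid triplets, and
   a per-liquid apolar diagnostic that exposes transposed angle columns
   in published tables.
2. **Coverage imaging.** Cell-occupied area fraction from grayscale
   micrographs: Otsu (or fixed) thresholding → morphological opening +
   small-object removal → 8-connected labeling → replicate mean ± sd.
3. **Enzymology.** Lipase activity from p-nitrophenyl-laurate hydrolysis
   kinetics (A410 vs time): least-squares initial rate, Beer–Lambert
   conversion to µmol p-nitrophenol/min (lipase units), specific
   activity per gram of cell debris, and activity retention after
   immobilization.

Assay bookkeeping (material × strain × pH × ionic strength × pronase
treatment), factorial tables, treatment contrasts and ionic-strength
profiles connect the imaging results to the experimental design.

## Worked example

Characterize PET from its three measured contact angles:

```r
library(adhesim)
liq <- probe_liquids()
pet <- solve_components(list(
  contact_angle(liq$water,            77.8, 1.3, 10),
  contact_angle(liq$formamide,        58.2, 1.8, 10),
  contact_angle(liq$methylene_iodide, 20.5, 2.2, 10)), "PET")
pet
#> <surface_energy> PET (mJ/m^2)
#>   gamma_LW  =   47.6
#>   gamma_+   =    0.2*
#>   gamma_-   =    8.1
#>   gamma_AB  =    2.8
#>   gamma_tot =   50.4
#>   (* component stored as squared magnitude of a negative root)

forward_contact_angle(pet, liq$water)   # 77.8 — the solve inverts exactly
classify_hydrophobicity(77.8)           # "hydrophobic"
```

PET's Lifshitz–van der Waals component is 47.6 mJ/m² with a very small,
negative-root-flagged electron-acceptor component (0.2) and modest
electron-donor component (8.1): a hydrophobic, weakly polar surface —
which is why it immobilizes less material than polystyrene.

Score coverage on synthetic micrographs with known truth:

```r
set <- gen_micrograph_set(micrograph_spec(true_coverage = 0.5, seed = 42),
                          n_images = 10, condition_id = "PS_pH7")
analyze_micrographs(lapply(set, `[[`, "image"))$per_condition
#>   condition_id mean_coverage sd_coverage n_images
#> 1       PS_pH7     0.5067551   0.0342954       10
```

The condition mean recovers the nominal 50% coverage to within the
replicate scatter (here sd ≈ 3.4% of area, inside the 2–10% band typical
of real assay images).

Lipase activity from a simulated kinetic trace:

```r
tr <- gen_kinetic_trace(0.0015, noise_sd = 0.002, seed = 42,
                        debris_mass = 0.05)       # 0.05 g debris, 25.1 mL
trace_activity(tr, epsilon = 10052)               # L / mol / cm at pH 7
#> <activity_result> sample: 0.222 U total, 4.448 U/g cell debris
```

Command-line use (thin wrapper over the same functions):

```sh
Rscript inst/cli/adhesim.R energy --angles angles.csv --out-dir out/
Rscript inst/cli/adhesim.R simulate --kind micrographs --seed 1 \
        --true-coverage 0.5 --out-dir sim/
Rscript inst/cli/adhesim.R coverage --manifest sim/manifest.csv --out-dir out/
```

Each run writes full-precision CSVs plus a JSON run-manifest (tool
version, config hash, input checksums); identical inputs give
byte-identical outputs.

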