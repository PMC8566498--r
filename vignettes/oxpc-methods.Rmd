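---
title: "Methods: oxPC structural libraries, annotation rules and 18O imaging support"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oxPC structural libraries, annotation rules and 18O imaging support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxpclib)
```

## Scope and model

Oxidized phosphatidylcholines (oxPCs) arise when reactive oxygen species
attack the polyunsaturated acyl chain (usually at *sn*-2) of a diacyl PC.
The products span full-length oxygenation classes — hydroperoxides,
epoxides/hydroxides, ketones, dehydro variants — and chain-truncated species
ending in an aldehyde or carboxylic acid. `oxpclib` provides the desk-scale
machinery for studying them by high-resolution LC-MS/MS and MALDI-MS/MS
imaging:

1. exact-mass arithmetic for PC ions (`monoisotopic_mass()`, `adduct_mz()`,
   `apply_heavy_oxygen()`, `ppm_error()`);
2. a shorthand-name grammar and a modification catalogue that expands into a
   structural library with rule-predicted diagnostic fragments
   (`parse_shorthand()`, `default_catalogue()`, `expand_catalogue()`,
   `predict_fragments()`);
3. a simplified nontargeted differential workflow (`detect_features()`,
   `align_runs()`, `group_adducts()`, `background_subtract()`,
   `extract_eic()`);
4. rule-based annotation (`match_precursor()`, `annotate_msms()`,
   `discriminate_functional_isomer()`);
5. internal-standard semiquantification and heat-map normalization
   (`semiquantify()`, `oxpc_fraction()`, `normalize_matrix()`);
6. heavy-oxygen labeling support for imaging (`labeled_transition()`,
   `estimate_labeling_efficiency()`, `render_ion_image()`,
   `artificial_oxidation_screen()`);
7. a synthetic-data module generating every input with known ground truth
   (`simulate_pair()`, `simulate_msms()`, `simulate_envelope()`,
   `simulate_msi()`).

## Mass conventions

Isotope masses come from the IUPAC/CODATA tables (`isotope_masses()`);
deuterium and oxygen-18 are tracked as their own symbols (`[2H]`, `[18O]` in
formula strings). Ion m/z values include the electron mass — anions gain an
electron, cations lose one — folded into the proton constant 1.00728 Da and
the formate-anion constant 44.99820 Da. All ions are singly charged; PC ions
of higher charge are not modeled and multiply charged precursors are
rejected at parse time.

PCs ionize in negative mode as formate adducts `[M+HCOO]-` in
ammonium-formate mobile phases; species whose oxidized chain carries a free
carboxyl terminus ionize directly as `[M-H]-`. Positive mode uses `[M+H]+`.
Two display conventions coexist: high-resolution m/z values print with 4
decimals (`mz_hrms()`), while nominal ion-trap transition values truncate to
1 decimal (`mz_nominal()`). Truncation — not rounding — is deliberate: the
published transition pairs (794.5 → 774.5 and the unlabeled 790.5 → 772.5)
are floor-truncated values of 794.5678/774.5529 and 790.5593/772.5487.

## The shorthand grammar

Names follow `PC<c>:<d>[/|_]<c>:<d>[;suffix...]`, with `/` marking known
sn-positions and `_` unknown ones. Suffix tokens compose: `O`/`O2`/`O3` add
oxygens (naming the epoxide/hydroxide series when written bare), `OOH` is
the hydroperoxide, `oxo` a ketone (one O, two fewer H), `On-H2` the dehydro
classes, and `CHO`/`COOH` mark truncated aldehyde/carboxyl termini (each
consuming one/two added oxygens and two hydrogens). The acyl free-acid
composition is `C(c) H(2c - 2d + h_delta) O(2 + added_O)`; a species is the
glycerophosphocholine backbone C8H20NO6P plus both acyl acids minus two
waters.

A deliberate asymmetry: a bare `;O2` parses to the epoxide/hydroxide class
because the hydroperoxide isomer has its own token (`;OOH`). The two are
isobaric and share every negative-mode fragment; they are distinct catalogue
entries distinguished only by functional class and their positive-mode
neutral loss (water vs hydrogen peroxide).

## The default catalogue (155 entries) and library (465 entries)

The shipped catalogue enumerates oxidation products of the three major
PUFAs (linoleate 18:2, arachidonate 20:4, docosahexaenoate 22:6):

* **Full-length classes**, nine per PUFA: `O-H2`, `O`, `oxo`, `O2-H2`,
  `OOH`, `O2` (epoxy/hydroxide), `O3-H2`, `O3`, `O4` — 27 entries.
* **Truncated chains** from beta-scission around each parent double bond: a
  double bond at carbon *p* yields chains of length *p* − 1, *p* and
  *p* + 1 with aldehyde (`CHO`) or carboxyl (`COOH`) termini, retaining the
  double bonds fully contained in the shortened chain. Deduplicated across
  parents this gives 28 (carbons, double-bond) pairs, 56 entries.
* **Oxygenated truncated variants**: hydroxy (`;O`) variants of both termini
  and keto (`;oxo`) variants of the carboxyl series, for chains with at
  least six carbons (shorter chains have no methylene left to carry a
  mid-chain oxygen between the two termini) — 72 entries.

The total is 155 distinct entries. The published full membership of the
source inventory is a supplementary dataset that is not reproduced in any
main text; only the total count, the class taxonomy and exemplar structures
are anchored, so this enumeration is the package's own convention chosen to
match the documented taxonomy at the documented size. Expansion over the
sn-1 chains 16:0, 18:0 and 18:1 — saturated and monounsaturated chains
resist oxidation, so structures transfer across sn-1 partners — yields
exactly 155 × 3 = 465 library entries whose names round-trip through the
parser.

Retention-class tags are coarse windows (truncated species elute early,
higher oxygen counts elute earlier than lower ones) used only by the
synthetic generator; provenance tags record the class-typical inducer
(hydroperoxides from radical initiators, secondary products from
metal-catalyzed decomposition).

## Fragmentation rules

Negative mode, from the formate adduct: (R1) the sn-1 carboxylate anion,
(R2) the oxidized-acyl carboxylate `[oxFA]-`, (R3) its water loss, and (R4)
the demethylated ion `[M-CH3]-`. R4 is computed as formate adduct minus
methyl formate (60.0211 Da) — the standard PC head-group demethylation
channel; the conventional label `[M-CH3]-` is kept as a label only.
Carboxyl-terminal species fragment from `[M-H]-` instead: (R5) loss of
trimethylamine (59.0735 Da) and (R6) the methylated oxidized acyl
`[oxFA+CH2]-`, alongside R1/R2. Positive mode from `[M+H]+`: (R7) water loss
for epoxides/hydroxides and (R8) hydrogen-peroxide loss for hydroperoxides.
Catalogue rows may carry extra diagnostic anion compositions (rule `CAT`),
used here for the characterized linoleate epoxy-hydroxide regiochemistry
markers; positional isomers are otherwise out of scope.

Annotation (`annotate_msms()`) counts predicted fragments present within
the fragment tolerance and accepts a candidate only with sn-1 evidence plus
at least one oxidized-acyl or head-group ion — a floor that operationalizes
the "three typical product ions" manual procedure while tolerating spectra
with a missing ion. The carboxyl class call requires both R5 and R6.
Hydroperoxide vs epoxy-hydroxide is never called from negative mode; the
positive-mode neutral loss decides it, with the H2O2 loss taking precedence
because hydroperoxides can also dehydrate.

## Tolerances and thresholds

| parameter | default | unit | why |
|---|---|---|---|
| precursor tolerance | 5 | ppm | high-resolution Orbitrap-class accuracy |
| fragment tolerance | 10 | ppm | printed fragment values deviate up to ~6 ppm from theory (e.g. 139.1120 observed vs 139.1128 theoretical) |
| RT co-elution window | 0.1 | min | alignment/grouping window of the reimplemented workflow |
| S/N threshold | 3 | — | detection filter |
| minimum apex intensity | 10,000 | counts | detection filter |
| minimum scans per peak | 3 | scans | detection filter |
| minimum isotopologues | 1 | — | a +1.00336 Da partner must co-elute |
| oxidized/nonoxidized ratio | > 2.0 (strict) | — | background-subtraction screen |
| element bounds | C26H48NO6P … C60H130NO30P | — | PC-space plausibility window |
| artifact-screen fraction | 0.05 | — | light-channel control signal vs labeled channel |

RT windows are symmetric (±); chromatography has no natural orientation.
A compound absent from the background (area 0) is retained by
`background_subtract()` — the screen is a presence filter, and division by
zero must not silently drop real oxidation products.

## Numerical and design choices

* **Alignment.** The vendor "adaptive curve" warp is proprietary and
  undocumented; the scientific content of the step is its tolerances, so the
  package uses a median shift estimated from mutual best m/z matches
  (within an anchor window, default 1 min) followed by tolerance gating.
  With `estimate_shift = FALSE` the gate applies to raw retention times; a
  constant shift larger than the window then yields no pairs, while with
  estimation the pairing is restored.
* **Local noise** for S/N is the median intensity of same-m/z-window
  centroids outside the candidate chain, floored at 1 — deterministic and
  desk-scale.
* **Grouping ties.** Greedy grouping proceeds by descending area, which
  makes memberships independent of input order.
* **Autoscaling** uses the population (not sample) standard deviation, the
  convention of the common metabolomics heat-map tools. Values below an
  optional detection floor become missing, not zero, keeping log10 defined;
  no imputation is attempted.
* **Labeling efficiency.** No published formula accompanies the headline
  labeled-fraction percentage, so the package defines the estimator: the
  intensity-weighted labeled-atom fraction `sum(k Ik) / (n sum(Ik))`, the
  maximum-likelihood estimate under a binomial single-probability model
  (both added oxygens draw from the same O2 pool). It is validated only by
  simulation self-consistency: scale-invariant, and recovering the
  generating probability to ±0.02 at 10,000 ions and bias < 0.005 at 10^5.
* **Which oxygen departs.** For a doubly labeled epoxy-hydroxide the water
  loss is taken from the labeled pool (H2-18O, 20.0148 Da), the only choice
  consistent with the published nominal transition pairs (Δ = 20.0).
* **Degenerate inputs** error early and name the offender: negative element
  counts, unknown symbols, zero internal standards, constant rows in
  autoscaling, all-zero envelopes, negative image intensities.

## What the synthetic data emulates — and what it does not

`simulate_pair()` builds paired oxidized/nonoxidized negative-mode runs:
a shared matrix of eight nonoxidized PCs at equal mean abundance in both
runs, spiked oxPCs in the oxidized run only, Gaussian chromatographic peaks
(sd 0.05 min, ~10 points across the FWHM on a 0.012-min scan grid, in the
spirit of the >15-points-per-peak acquisition guidance), a 30% +1
isotopologue partner per compound, multiplicative log-normal abundance noise
(sd 10%), uniform single-scan noise centroids, and DDA-style MS/MS with
decoy peaks kept at least 20 ppm away from true fragments. Inducer presets
reweight the spiked classes (radical stress strongly favors hydroperoxides;
metal-catalyzed decomposition favors mono-/di-oxygenated and truncated
products). `simulate_msi()` produces uniform or pericentrally zonated
grids — disks of elevated signal around vein-like centers on a low
background — with a truth mask.

By default the spike pool excludes entries that are analytically
indistinguishable in the simulated channels: the dehydro/keto twins (`O-H2`
vs `oxo`) share composition, precursor adduct and every predicted fragment,
and no measurement the simulation produces can separate them
(`identifiable_only = TRUE`). The isobaric `OOH`/`O2` twins stay in the
pool because the attached positive-mode spectra separate them, exactly as
the two-step annotation procedure prescribes.

The generators do **not** emulate ion suppression, realistic isotope
envelopes beyond the +1 partner, profile peak shapes, co-eluting positional
isomers, or instrument drift. A clean pass of the pipeline-closure test
(≥95% of spiked species recovered by name) therefore demonstrates internal
consistency of detection → alignment → subtraction → annotation at the
documented tolerances, not performance on real tissue extracts.

Problem sizes used by the test suite and acceptance checks: 10–50 spikes
over ~1,100 scans per run, 40-entry annotation samples from the 465-entry
library, 10^4–10^5-ion envelopes, and 30×30 to 60×60 imaging grids —
sizes chosen so every property is exercised in seconds while the
statistical assertions retain comfortable margins.

## Semiquantification

All quantities are dimensionless area ratios against the deuterated
internal standard PC15:0/18:1-d7 (C41H73[2H]7NO8P, neutral 752.6061 Da,
`[M+H]+` 753.6134), spiked before extraction. Tissue wet weight enters as an
optional per-sample scalar divisor. The oxPC percentage is
`100 · Σ oxPC / (Σ oxPC + Σ PC)` per sample. Absolute quantitation with
calibration curves is out of scope.

## Known limitations

* Catalogue membership beyond the anchored taxonomy is a convention (above);
  regiochemistry is encoded only through optional catalogue fragments.
* Ether/plasmalogen PCs and other phospholipid classes are not modeled.
* Negative mode alone reports the isobaric `OOH`/`O2` pair jointly; a
  positive-mode spectrum is required to split it.
* The MGF and CSV interfaces are native; mzML reading requires the
  Bioconductor `mzR` package.

## A worked example

```{r example}
lib <- build_library()
nrow(lib)

predict_fragments("PC16:0_9:0;COOH", "neg", library = lib)

labeled_transition("PC16:0_18:2;O2", n_labels = 2, library = lib)[
  , c("precursor", "product")
]

sim <- simulate_pair(simulation_spec(seed = 1, n_spikes = 5, library = lib))
res <- run_pipeline(sim, library = lib)
res[, c("mz", "name", "score", "functional_class")]
mean(sim$truth$name %in% res$name)
```
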