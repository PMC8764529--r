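# coftools

Analysis toolkit for enzymology studies of the coenzyme F420 biosynthesis
pair CofC/FbiD (the guanylyltransferase that activates a C3 phospho-acid —
2-phospho-L-lactate, phosphoenolpyruvate or 3-phospho-D-glycerate — with
GTP) and CofD/FbiA (the transferase that moves the activated moiety onto
the deazaflavin core FO). It is written for structural biologists and
enzymologists who have the wet-lab data — ligand-bound crystal structures,
homolog alignments, LC-MS readouts of combined CofC/D activity assays,
nano-DSF melting curves — and need the quantitative analyses downstream of
them, reproducibly and with tests.

## What it computes

**Binding-site geometry.** The central statistic is the *out-of-pi-plane
distortion* of a hydrogen bond donated to an sp2 group: for the
total-least-squares plane of the group (normal **n**, centroid **c**), the
partner atom at **p** is off-plane by |(**p** − **c**) · **n**|, and
`average_pi_distortion()` averages this over a bond set — a strain measure
for carboxylate/amide hydrogen bonding that distinguishes favourable from
squeezed substrate poses. Around it: a fixed-column PDB reader/writer with
deterministic alt-loc resolution, heavy-atom H-bond detection (2.4–3.5 Å
window, no hydrogens needed), chain-averaged protein–ligand contact tables
with water/Mg bridge flagging, Kabsch (SVD) superposition with reflections
excluded, the rotation angle of a carboxylate about its O–O axis between
two superposed poses, per-atom group displacements, and metal-coordination
audits.

**Homolog screening.** Maps a reference residue (such as the
specificity-linked serine of 3-PG-activating CofC proteins) to its column
in any multiple alignment, then calls each homolog `tolerant` (S/T at the
column), `non_tolerant`, or `indeterminate` (gap). Needleman–Wunsch global
alignment and percent identity (identical pairs over columns with at least
one residue) cover the pairwise comparisons.

**Assay quantification.** The LC-MS chain for the combined CofC/D
competition assay: extracted ion chromatograms → trapezoidal peak areas
with linear baseline → normalisation → ordinary-least-squares rates over
the linear 0–20 min range → relative turnover per substrate,
r_i = 100·k_i/Σ_j k_j, with mean ± sample SD over replicates
(`quantify_assay()` runs the whole chain).

**Thermal-shift binding.** Two-state van 't Hoff unfolding
(ΔG_u = ΔH_u(1 − T/T_m), ΔCp = 0) with ligand linkage
ΔG_app = ΔG_u + RT ln(1 + L/K_D); joint Levenberg–Marquardt fits across a
titration recover K_D, and an RSS grid maps the feasible
(K_D,GTP, K_D,GPPG) combinations when part of the protein co-purifies with
tightly bound product.

**Synthetic data.** Seeded generators plant known truth for every stage:
toy binding pockets with exact out-of-plane offsets, ligand pose pairs
related by exact rotations, homolog sets with planted diagnostic residues,
chromatogram runs with known rates, melting curves with known K_D. They
are first-class, tested code — the whole pipeline validates against them
and against brute-force oracles without any downloads.

## Worked example

```r
library(coftools)

# a two-chain pocket with three donors planted at known out-of-plane offsets
pocket <- make_pocket(n_donors = 3, planted_pi_offsets = c(1.2, 1.4, 1.5),
                      ligand_template = "gppg", n_metals = 2, chains = 2,
                      jitter_sd = 0.05, seed = 42)
hb <- detect_hbonds(pocket$model, list(chain = "A", res_name = "GPG"))
average_pi_distortion(hb)

# triplicate competition assay at a 65 : 26.5 : 8.5 rate ratio, 2% noise
run <- make_assay_run(true_rates = c("3PG-F420-0" = 0.65, "F420-0" = 0.265,
                                     "DF420-0" = 0.085),
                      noise_cv = 0.02, n_replicates = 3, seed = 1)
q <- quantify_assay(run$chromatograms, window = c(0, 20))
q$profile

# K_D from a simulated nano-DSF titration (true K_D = 10 uM)
truth <- unfolding_model(T_m = 320, dH_u = 300, K_D = 10e-6)
dc <- make_dsf_curves(truth, ligand_concs = c(0, 2e-6, 10e-6, 50e-6),
                      noise_sd = 0.005, seed = 2)
fit_melting(dc$curves, seed = 2)$estimates
```

This prints (exact numbers depend only on the seeds shown):

```
mean out-of-plane distortion: 1.367 A

  substrate mean_turnover_pct sd_turnover_pct n_replicates
1      3-PG             65.14           0.607            3
2       PEP              8.39           0.203            3
3      2-PL             26.47           0.536            3

  parameter  estimate        se     ci_lo     ci_hi
1       T_m 3.200e+02 3.430e-02 3.199e+02 3.201e+02
2      dH_u 2.997e+02 1.816e+00 2.962e+02 3.033e+02
3       K_D 1.021e-05 2.708e-07 9.677e-06 1.074e-05
```

The H-bond table carries each planted offset back out exactly; the
turnover profile recovers the generator's 65 / 26.5 / 8.5 percent split
within the noise; the melting fit returns K_D ≈ 10 µM with its asymptotic
95% confidence interval.

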