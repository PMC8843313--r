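# covkin

Kinetic and structural analysis of covalent-reversible enzyme inhibition,
built around the cathepsin K / cyanohydrazide system: warheads that form a
covalent but reversible adduct with the catalytic cysteine, producing
either **slow-binding** kinetics (curved progress plots, analysed through
the observed rate constant *k*<sub>obs</sub>) or **fast, tight-binding**
kinetics (linear progress plots at inhibitor concentrations comparable to
the enzyme concentration, analysed with the Morrison equation). The
package is for enzymologists and medicinal chemists who want the whole
chain — mechanistic simulation, curve fitting, corrections, reporting —
as tested, reusable code.

## The models

Slow-binding progress curves and their secondary analysis:

    P(t)   = v_s t + (v_i - v_s) (1 - exp(-k_obs t)) / k_obs + d
    k_obs  = k'_on [I] + k_off
    k_on   = k'_on (1 + [S]/K_m)
    v_s/v0 = 1 / (1 + [I]/K_i')          K_i = K_i' / (1 + [S]/K_m)

Tight-binding (Morrison) dose-response with enzyme depletion:

    v_s/v0 = 1 - [ (E0 + I + K_i') - sqrt((E0 + I + K_i')^2 - 4 E0 I) ] / (2 E0)

and the thermodynamic closure `K_i = k_off / k_on`. The synthetic-data
generator integrates the full mass-action mechanism (E + S ⇌ ES → E + P,
E + I ⇌ EI) rather than these closed forms, so parameter recovery through
the analysis chain is a real test of the estimation procedures. A
structural module implements the contact criteria used on the deposited
complexes (hydrogen-bond candidates at 3.3 Å between N/O/S atoms,
nonpolar contacts at 4.2 Å between hydrophobic carbons), Kabsch backbone
superposition RMSD, ligand RMSD in the superposed frame, and ligand
B-factor profiling.

## Worked example

Simulate the reference fluorogenic assay (20 µM substrate, K_m = 17.4 µM,
0.42 nM enzyme, 40 min) for the two literature inhibitors and analyse it
end to end:

```r
library(covkin)

curves <- simulate_progress_curves(params_gu1303(), assay_conditions(),
                                   inhibitor_grid("slow"))
analyze_inhibition(curves, compound = "Gu1303")
#> Inhibition analysis of Gu1303: slow_binding
#>   Ki    = 0.949 +/- 0.0052 nM
#>   kon   = 525.4 +/- 0.41 x10^3 /(M s)
#>   koff  = 0.466 +/- 0.0095 x10^-3 /s
#>   (koff/kon = 0.887 nM)

tight <- simulate_progress_curves(params_gu2602(), assay_conditions(),
                                  inhibitor_grid("tight"))
analyze_inhibition(tight, compound = "Gu2602")
#> Inhibition analysis of Gu2602: fast_binding
#>   Ki    = 0.0131 +/- 1.8e-05 nM
#>   kon, koff: n.d.: not determined for linear progress curves
```

The slow binder is classified from its curved progress plots, each curve
is fitted for *k*<sub>obs</sub>, the *k*<sub>obs</sub>-vs-[I] line gives
the association (slope, corrected by 1 + [S]/K_m) and dissociation
(intercept) rate constants, and the steady-state fractions give K_i via
Cheng-Prusoff — recovering the generating constants (K_i = 0.91 nM,
k_on = 527×10³ M⁻¹s⁻¹, k_off = 0.48×10⁻³ s⁻¹) to within a few percent;
the small residual bias is the physical inhibitor-depletion effect
discussed in the vignette. The tight binder's linear curves route to the
Morrison fit instead, and its rate constants are correctly reported as
not determined.

## Analysis workflow

The `analysis/` directory holds the numbered drivers of the full study:

1. `01_simulate_assays.R` — noisy progress-curve sets, a Michaelis-Menten
   rate table and an active-site titration, written under `results/sim/`.
2. `02_fit_kinetics.R` — recovers K_m, the active enzyme concentration
   and both inhibitors' constants; writes the Table-style report
   `results/inhibition_report.csv`.
3. `03_autoactivation.R` — qualitative zymogen-autoactivation suppression
   across an inhibitor-affinity grid.
4. `04_structure_contacts.R` — contact lists, superposition RMSD, ligand
   RMSD and B-factor profile on the packaged synthetic complex pair.

Run them in order from the repository root with `Rscript`.

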