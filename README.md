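# exoprofiler

Simulation and analysis of **exonuclease-protection profiling** for
aptamer–small-molecule binding.

Aptamer candidates coming out of an in vitro selection need their binding
profiles characterised — affinity for the target, cross-reactivity against
interferents — and one-pair-at-a-time methods (ITC, SPR) do not scale to
dozens of candidates. Exonuclease protection turns binding into a kinetic
signature: a ligand-bound aptamer stalls exonucleolytic digestion, leaving
a persistent truncated product, while the free aptamer is digested to
completion at an exponential rate. A dye-based fluorescence time course
read in microplates quantifies retained DNA, and the **resistance value**

    R = (AUC1 − AUC0) / AUC0

(areas under the time course with and without ligand) reports binding
strength on a scale-free axis: R ≈ 0 for non-binders, R ≈ 0.8–1 for true
binders under the standard screen. Cross-reactivity of a test ligand L
relative to the main target T is `CR = 100 (AUC_L − AUC0)/(AUC_T − AUC0)`,
and concentration series of R yield an apparent half-saturation constant
via `R(c) = Rmax · c/(k_half + c)`.

The package provides, for users building or evaluating such screens:

- a mechanistic simulator of digestion time courses (slow/fast exchange,
  protected-product plateau ω = P/N, constant-CV plate noise, deterministic
  per-well sub-seeds) and of the strand-displacement fluorophore-quencher
  readout including ligand–dye artifact failure modes;
- the AUC / resistance / cross-reactivity / signal-gain statistics with
  replicate aggregation and time-grid alignment;
- binder calling for candidate panels, cross-reactivity profiling, and
  constrained dose-response fitting with bootstrap CIs;
- long-format CSV and attribute-tagged FASTA I/O for plates and panels.

## Worked example

Screen the bundled synthetic 29-candidate panel (4 true binders among 25
non-binders) at 200 µM target, then call binders:

```r
library(exoprofiler)

panel <- mephedrone_screen_panel()
plate <- simulate_panel(panel$aptamers,
                        list(ligand_condition("mephedrone", 200)),
                        panel$binding_table, n_replicates = 2,
                        params = digestion_params(noise_cv = 0.05),
                        seed = 20260926)
calls <- call_binders(resistance_table(plate), threshold = 0.1)
head(calls, 5)
```

```
# A tibble: 5 × 6
  aptamer_id resistance_mean resistance_sd call       threshold_used z_pass
  <chr>                <dbl>         <dbl> <chr>               <dbl> <lgl>
1 MMC3                0.924         0.0246 binder                0.1 TRUE
2 MMC2                0.899         0.0716 binder                0.1 TRUE
3 MMC1                0.885         0.0349 binder                0.1 TRUE
4 MMC4                0.809         0.0244 binder                0.1 TRUE
5 MMC9                0.0365        0.0332 non-binder            0.1 FALSE
```

Exactly the four generating binders (MMC1–4, apparent Kd 6.6–40 µM) are
called, with resistance values in the 0.8–1 band expected for true binders
and every non-binder within a few percent of zero. The same machinery
drives the numbered drivers under `analysis/`: `01` simulates the screen,
specificity and calibration plates and writes time-course CSVs to
`results/`; `02` builds the cross-reactivity profile (reference = 100%, a
10-fold-weaker analog lands in between, non-binders are annotated not
significant); `03` makes the screen calls; `04` fits the dose-response
(`k_half = 95.6 µM`, bootstrap 95% CI `[90.6, 101.1]`, truth 100 µM); `05`
tabulates the digestion-vs-strand-displacement comparison, flagging the
chlorpromazine-like false negative (R = 0.97 but SD gain −0.21) and the
acetyl-fentanyl-like false positive (R ≈ 0 but SD gain +0.31).

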