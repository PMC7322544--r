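# Packaged data schema

All fixture CSVs are UTF-8, comma-separated, "." decimal. Cells keep the
source tables' literal conventions: `ND` = no IC50 determined (<10%
inhibition at the highest tested concentration, 30 uM); `NA` = not tested /
not applicable; `>x` = right-censored concentration (no effect up to x).
All concentrations are uM; in-vivo concentrations are free plasma.

## table3_panels.csv (ion-channel potency panels, compounds 1-73)
- `nce`: compound number
- `px_herg_ic50`: PatchXpress hERG (IKr) IC50
- `px_hnav15_ic50`: PatchXpress hNav1.5 (INa) IC50
- `px_iks_ic50`: PatchXpress IKs (KCNQ1/KCNE1) IC50
- `hts_hcav12_ic50`: high-throughput hCav1.2 FLIPR (ICaL) IC50
- `hts_mk499_ic50`: high-throughput MK-499 binding (IKr) IC50
- `hts_hnav15_ic50`: high-throughput hNav1.5 FLIPR (INa) IC50

## table4_margin.csv (IC20 safety-margin stage)
- `nce`: compound number
- `qtc_ec5`: guinea-pig QTc EC5 (or `>cmax` when no QTc effect was seen)
- `px_herg_ic20`: PatchXpress hERG IC20
- `px_label`: printed confusion label for the PX margin comparison
- `hts_mk499_ic20`: MK-499 IC20 (may be `ND`, `NA` or `>30`)
- `hts_label`: printed confusion label for the HTS margin comparison

## table5_insilico_tpkpd.csv (in-silico directional + tPKPD stage)
- `nce`, `qtc_ec5`: as above
- `px_apd90_dir`, `px_emw_dir`: simulated APD90 / EMw directional effect
  using PX ion-channel inputs (`up`, `down`, `down-up`, `up-down`; `NA`
  when not simulated or not legible in the source)
- `px_insilico_label`: printed confusion label, in-silico stage
- `px_tpkpd_ec5`: tPKPD-projected QTc EC5 using PX inputs
- `px_adjusted_label`: printed confusion label after tPKPD adjustment
- `hts_*`: the same five columns for the HTS inputs

## feature_spec.csv (tPKPD feature layout; configuration, not data)
- `approach`: PX or HTS
- `kind`: `potency` or `simulated`
- `assay`, `channel`, `transform` (`pic50` or `hill`): potency features
- `biomarker`, `rank`: simulated population-mean features; rank 1 is the
  highest non-zero tested concentration

## calibration_ranges.csv (population calibration; configuration)
- `biomarker`, `low`, `high`: control-biomarker acceptance window
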