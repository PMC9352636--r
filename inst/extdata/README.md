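# reference_config.json

The canonical reference-individual configuration consumed by
`load_parameter_set()`. JSON carries no comments, so units and provenance are
summarised here.

Units (the package's fixed internal system): amounts µmol, volumes L, flows
L/h, time h, masses g, concentrations µM, doses mg at the boundary.

| group | key | unit | note |
|---|---|---|---|
| physchem.* | pKa, logP | – | descriptive only |
| physchem.* | MW | g/mol | dose conversion |
| physchem.* | fu | fraction | informational (binding is carried by the partition coefficients) |
| physchem.* | BP | – | blood:plasma ratio |
| physiology | BW | kg | body weight |
| physiology | Hep | 10^6 cells/g | hepatocellularity |
| physiology | MPPGL | mg/g | microsomal protein per g liver |
| physiology | V*c | L/kg | tissue volumes per kg BW (VLc·1000 = liver g/kg) |
| physiology | QCc | L/h/kg^0.74 | cardiac output coefficient |
| physiology | Q*c | fraction | regional flow fractions of cardiac output |
| ba | synthesis, fecal_excretion | µmol/h | fecal tied to synthesis |
| ba | CBfs | µM | fasting plasma bile-acid level |
| ba | Gdose | µmol | full gall bladder; set so the initial pool totals 3079 µmol |
| ba | QIb | fraction | biliary split: direct-to-lumen share |
| ba | ka | 1/h | intestinal absorption (fitted-class parameter) |
| ba | Km_BSEP | µM | BSEP Michaelis constant (free liver concentration) |
| ba | VmaxBSEPc | µmol/min/mg BSEP | in vitro transport capacity |
| ba | aBSEP | pmol/10^6 cells | BSEP abundance (population mean = 1.0 reference) |
| ba | MW_BSEP | g/mol | 140 kDa |
| ba | partition.* | – | tissue:plasma partition coefficients |
| drug | ODOSEmg | mg | oral bosentan dose |
| drug | Fa | fraction | absorbed fraction |
| drug | ka_drug, kbile_* | 1/h | first-order constants (fitted class) |
| drug | Km_met | µM; VmaxMc µmol/min/mg; CLMc L/h/10^6 cells | hepatic metabolism |
| drug | frm | fraction | bosentan turnover routed to RO 47-8634 |
| drug | Ki_bosentan, Ki_ro | µM | non-competitive inhibition constants |
| schedule | meal_times, dose_times | clock h | events repeat daily |

Provenance: printed literature values are used directly (synthesis, pool,
CBfs, liver weight rule, Hep, MPPGL, MW_BSEP, Ki values, physicochemistry).
All remaining values are a **synthetic reconstruction** — the original
supplementary model code is not redistributed here — anchored to the cited
assay/meta-analysis ranges and calibrated once against the published
reference outputs (see the methods vignette, section "Parameter provenance
and calibration").
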