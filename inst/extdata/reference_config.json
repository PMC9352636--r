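{
  "physchem": {
    "ba": {
      "pKa": 3.77,
      "logP": 2.12,
      "MW": 449.62,
      "fu": 0.01,
      "BP": 0.55
    },
    "bosentan": {
      "pKa": 5.46,
      "logP": 3.1,
      "MW": 551.6,
      "fu": 0.02,
      "BP": 0.6
    },
    "ro": {
      "pKa": 5.46,
      "logP": 3.1,
      "MW": 551.6,
      "fu": 0.02,
      "BP": 0.55
    }
  },
  "physiology": {
    "BW": 70,
    "Hep": 99,
    "MPPGL": 32,
    "VBc": 0.079,
    "VLc": 0.02,
    "VITc": 0.017,
    "VRc": 0.047,
    "VSc": 0.51,
    "VFc": 0.214,
    "QCc": 15,
    "QLac": 0.046,
    "QITc": 0.181,
    "QRc": 0.481,
    "QSc": 0.24,
    "QFc": 0.052
  },
  "ba": {
    "synthesis": 46.8,
    "fecal_excretion": 46.8,
    "CBfs": 2.4,
    "Gdose": 3071.7004,
    "QIb": 0.5,
    "ka": 0.17,
    "Km_BSEP": 9,
    "VmaxBSEPc": 1.438,
    "aBSEP": 1,
    "MW_BSEP": 140000,
    "partition": {
      "liver": 0.111,
      "intestine": 0.53,
      "rapid": 0.23,
      "slow": 0.15,
      "fat": 0.076
    }
  },
  "drug": {
    "ODOSEmg": 500,
    "Fa": 0.5,
    "ka_drug": 0.74,
    "Km_met": 9,
    "VmaxMc": 9.3e-05,
    "CLMc": 0.000187,
    "frm": 0.59,
    "kbile_bosentan": 0.15,
    "kbile_ro": 44,
    "Ki_bosentan": 12,
    "Ki_ro": 8.5,
    "partition_bosentan": {
      "liver": 2.1,
      "rapid": 0.8,
      "slow": 0.5,
      "fat": 0.7
    },
    "partition_ro": {
      "liver": 1,
      "rapid": 0.8,
      "slow": 0.5,
      "fat": 0.7
    }
  },
  "schedule": {
    "meal_times": [8, 12, 16],
    "dose_times": [8, 20],
    "simulation_days": 3
  },
  "sens": 1
}
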