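{
  "diet": ["Folivore", "Frugivore", "Generalist", "Granivore", "Invertivore",
           "Nectarivore", "Piscivore", "Scavenger", "TetrapodHunter"],
  "column": ["PlantO", "Fruit", null, "Seed", "Inv", "Nect", "Fish", "Scav",
             "Tetr"],
  "standard": [80, 80, 30, 90, 90, 80, 70, 100, 80],
  "semi": [60, 60, 40, 70, 60, 60, 50, 50, 60],
  "_comment": "Thresholds are percent of diet, read inclusively (>=); the Generalist row gives the maximum any single category may reach."
}
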