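{
  "physio": {"BW": 5, "QCC": 19.8, "QfilC": 0.15, "VfilC": 4e-04},
  "chemical": {"bioAv": 0.9, "VCC": 0.24, "Tmc": 2.5, "Kt": 0.004,
               "Free": 0.0045, "k12": 3.3, "k21": 3.4, "ka": 132},
  "half_life_years": null
}
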