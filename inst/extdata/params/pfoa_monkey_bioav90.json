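{
  "physio": {"BW": 4.1, "QCC": 19.8, "QfilC": 0.15, "VfilC": 4e-04},
  "chemical": {"bioAv": 0.9, "VCC": 0.23, "Tmc": 0.15, "Kt": 0.008,
               "Free": 0.0012, "k12": 3.3, "k21": 3.4, "ka": 230},
  "half_life_years": null
}
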