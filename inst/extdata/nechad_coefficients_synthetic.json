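{
  "_comment": "SYNTHETIC test fixture. Per-band amplitude (A_t, FNU) and reflectance asymptote (C_t) pairs for the single-band turbidity model are user-supplied calibration inputs; these values are illustrative, of the published order of magnitude, and are NOT an operational look-up table.",
  "olci": {
    "b665": {"A_t": 355.85, "C_t": 0.1728},
    "b708": {"A_t": 567.23, "C_t": 0.1886},
    "b778": {"A_t": 1154.04, "C_t": 0.2115},
    "b865": {"A_t": 1913.65, "C_t": 0.2115}
  },
  "msi": {
    "b665": {"A_t": 355.85, "C_t": 0.1728},
    "b708": {"A_t": 567.23, "C_t": 0.1886},
    "b778": {"A_t": 1154.04, "C_t": 0.2115},
    "b865": {"A_t": 1913.65, "C_t": 0.2115}
  }
}
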