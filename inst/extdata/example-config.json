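{
  "schema": "enterosim-config",
  "schema_version": "1.0",
  "lumen": {"glucose": 50},
  "blood": {"flow": 2e-17, "inflow": {"glucose": 8}},
  "glut2_apical": {"n_copies": 5e7},
  "protocol": {
    "t_end": 8000,
    "record_dt": 40,
    "events": [
      {"time": 0,    "lumen": {"glucose": 0}},
      {"time": 4000, "lumen": {"glucose": 50}}
    ]
  }
}
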