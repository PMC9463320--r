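{
  "seed": 7,
  "stages": ["simulate", "register", "localize", "evaluate"],
  "pose": {
    "primary_angle_deg": 30,
    "secondary_angle_deg": 0,
    "sod_mm": 750,
    "sid_mm": 1000
  },
  "second_pose": {
    "primary_angle_deg": -15,
    "secondary_angle_deg": 0,
    "sod_mm": 750,
    "sid_mm": 1000
  },
  "phantom": {
    "marker_radial_offset_mm": 0
  },
  "localization": {
    "spacing_mm": 0.5,
    "quantize": true
  }
}
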