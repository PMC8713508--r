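{
  "n_decedents": 50,
  "signs": {
    "sign": ["resp_verbal_decreased", "resp_visual_decreased",
             "peripheral_cyanosis", "mandibular_respiration", "death_rattle",
             "neck_hyperextension", "eyes_unable_to_close",
             "nasolabial_drooping", "cheyne_stokes", "pulseless_radial",
             "apnea"],
    "n_within72h": [38, 37, 16, 22, 15, 14, 11, 12, 8, 20, 0],
    "mort72_num": [29, 28, 16, 21, 13, 8, 11, 8, 4, 20, null],
    "mort72_den": [38, 37, 16, 22, 15, 14, 11, 12, 8, 20, null],
    "mort24_num": [18, 16, 10, 14, 10, 5, 8, 7, 2, 17, null],
    "mort24_den": [38, 37, 16, 22, 15, 14, 11, 12, 8, 20, null],
    "median_onset_days": [2.0, 2.0, 1.0, 1.0, 1.0, 3.0, 1.0, 1.0, 2.5, 0.5, null]
  }
}
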