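{
  "participant_id": "ID",
  "fascicle_length_rest0": "Lf_rest0_mm",
  "pennation_rest0": "PA_rest0_deg",
  "thickness_rest0": "MT_rest0_mm",
  "fascicle_length_rest60": "Lf_rest60_mm",
  "pennation_rest60": "PA_rest60_deg",
  "thickness_rest60": "MT_rest60_mm",
  "fascicle_length_mvc60": "Lf_mvc60_mm",
  "pennation_mvc60": "PA_mvc60_deg",
  "thickness_mvc60": "MT_mvc60_mm",
  "force_max": "Fmax_N",
  "force_iso400": "Fiso400_N",
  "G": "G_curv",
  "L0": "L0_mm",
  "joint_work_100": "Wjoint_100_J"
}
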