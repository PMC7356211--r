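{
  "schema": "nwr-session-1",
  "required": ["schema", "subject_id", "group", "limb", "seed", "stimuli",
               "status", "success_intensities_mA", "threshold_mA",
               "mean_rating"],
  "nullable": ["threshold_mA", "mean_rating"],
  "stimulus_fields": ["ordinal", "time_s", "intensity_mA", "z_score",
                      "is_response", "rating"],
  "statuses": ["OK", "CAP_REACHED", "ABORTED"],
  "limbs": ["first", "second"]
}
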