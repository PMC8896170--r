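{
  "myocardial_infarction": ["410", "412"],
  "congestive_heart_failure": ["428"],
  "peripheral_vascular_disease": ["441", "443.9", "447.1", "785.4", "V43.4"],
  "cerebrovascular_disease": ["430", "431", "432", "433", "434", "435", "436", "437", "438"],
  "dementia": ["290"],
  "chronic_pulmonary_disease": ["490", "491", "492", "493", "494", "495", "496", "500", "501", "502", "503", "504", "505"],
  "rheumatologic_disease": ["710.0", "710.1", "710.4", "714.0", "714.1", "714.2", "714.81", "725"],
  "peptic_ulcer_disease": ["531", "532", "533", "534"],
  "mild_liver_disease": ["571.2", "571.4", "571.5", "571.6"],
  "diabetes": ["250.0", "250.1", "250.2", "250.3", "250.7"],
  "diabetes_with_complications": ["250.4", "250.5", "250.6"],
  "hemiplegia_paraplegia": ["342", "344.1"],
  "renal_disease": ["582", "583", "585", "586", "588"],
  "moderate_severe_liver_disease": ["456.0", "456.1", "456.2", "572.2", "572.3", "572.4", "572.8"],
  "aids": ["042", "043", "044"]
}
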