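{
  "HCM": ["HCM", "NOONAN_RASOPATHY", "FABRY"],
  "DCM": ["HCM", "DCM", "ARVD_C", "DMD_BECKER"],
  "UNSPECIFIED_CARDIOMYOPATHY": ["HCM", "DCM", "ARVD_C", "NOONAN_RASOPATHY", "FABRY", "DMD_BECKER"],
  "ARVD_C": ["DCM", "ARVD_C", "BRUGADA", "CPVT", "UNSPECIFIED_ARRHYTHMIA"],
  "UNSPECIFIED_ARRHYTHMIA": ["HCM", "DCM", "ARVD_C", "LQTS", "SQTS", "BRUGADA", "CPVT", "UNSPECIFIED_ARRHYTHMIA"]
}
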