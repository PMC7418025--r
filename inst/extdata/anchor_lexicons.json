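{
  "critical_events": {
    "入院": "ADMISSION",
    "出院": "DISCHARGE",
    "手术": "SURGERY",
    "术后": "SURGERY",
    "术": "SURGERY",
    "化疗": "CHEMOTHERAPY",
    "放疗": "CHEMOTHERAPY",
    "返院": "RETURN",
    "回院": "RETURN"
  },
  "section_phrases": {
    "出院医嘱": "DISCHARGE",
    "出院情况": "DISCHARGE",
    "出院诊断": "DISCHARGE",
    "入院诊断": "ADMISSION",
    "入院情况": "ADMISSION"
  }
}
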