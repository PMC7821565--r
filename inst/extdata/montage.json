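{
  "description": "15-channel prefrontal fNIRS montage: optode pairs (10/20 system), Brodmann areas, and region-of-interest membership.",
  "wavelengths_nm": [760, 850],
  "source_detector_distance_mm": 30,
  "channels": [
    {"channel": 1,  "optodes": "F5/F7",   "brodmann": "47/46", "roi": "left"},
    {"channel": 2,  "optodes": "AF7/F5",  "brodmann": "46",    "roi": "left"},
    {"channel": 3,  "optodes": "AF7/AF3", "brodmann": "46/9",  "roi": "left"},
    {"channel": 4,  "optodes": "F3/F5",   "brodmann": "46/8",  "roi": "left"},
    {"channel": 5,  "optodes": "F3/AF3",  "brodmann": "8/9",   "roi": "left"},
    {"channel": 6,  "optodes": "F1/F3",   "brodmann": "8",     "roi": "central"},
    {"channel": 7,  "optodes": "Fz/F1",   "brodmann": "8",     "roi": "central"},
    {"channel": 8,  "optodes": "Fz/AFz",  "brodmann": "8/9",   "roi": "central"},
    {"channel": 9,  "optodes": "Fz/F2",   "brodmann": "8",     "roi": "central"},
    {"channel": 10, "optodes": "F2/F4",   "brodmann": "8",     "roi": "central"},
    {"channel": 11, "optodes": "F4/AF4",  "brodmann": "8/9",   "roi": "right"},
    {"channel": 12, "optodes": "F4/F6",   "brodmann": "8/46",  "roi": "right"},
    {"channel": 13, "optodes": "AF4/AF8", "brodmann": "9/46",  "roi": "right"},
    {"channel": 14, "optodes": "AF8/F6",  "brodmann": "46",    "roi": "right"},
    {"channel": 15, "optodes": "F6/F8",   "brodmann": "46/45", "roi": "right"}
  ]
}
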