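{
  "comment": "Five-tier combining rules over evidence strength categories. Each entry is a minimum-count pattern; a verdict applies when any of its patterns is met. Categories: PVS (very strong), PS (strong), PM (moderate), PP (supporting), BA (stand-alone benign), BS (strong benign), BP (supporting benign). Conflicting pathogenic- and benign-direction evidence is resolved to VUS by the combiner, not here.",
  "version": 1,
  "pathogenic": [
    {"PVS": 1, "PS": 1},
    {"PVS": 1, "PM": 2},
    {"PVS": 1, "PM": 1, "PP": 1},
    {"PVS": 1, "PP": 2},
    {"PS": 2},
    {"PS": 1, "PM": 3},
    {"PS": 1, "PM": 2, "PP": 2},
    {"PS": 1, "PM": 1, "PP": 4}
  ],
  "likely_pathogenic": [
    {"PVS": 1, "PM": 1},
    {"PS": 1, "PM": 1},
    {"PS": 1, "PP": 2},
    {"PM": 3},
    {"PM": 2, "PP": 2},
    {"PM": 1, "PP": 4}
  ],
  "benign": [
    {"BA": 1},
    {"BS": 2}
  ],
  "likely_benign": [
    {"BS": 1, "BP": 1},
    {"BP": 2}
  ]
}
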