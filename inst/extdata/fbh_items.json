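{
  "scale": "feeling_being_heard",
  "response_scale": "7-point, 'not at all' via 'neutral' to 'very much'",
  "items": [
    {"id": "fbh_1", "origin": "patient satisfaction questionnaire (adapted)", "text": "<placeholder: satisfaction item 1, adapted to the virtual agent>"},
    {"id": "fbh_2", "origin": "patient satisfaction questionnaire (adapted)", "text": "<placeholder: satisfaction item 4, adapted to the virtual agent>"},
    {"id": "fbh_3", "origin": "trust-in-physician scale (adapted)", "text": "<placeholder: trust item 5, adapted to the virtual agent>"},
    {"id": "fbh_4", "origin": "trust-in-physician scale (adapted)", "text": "<placeholder: trust item 8, adapted to the virtual agent>"},
    {"id": "fbh_5", "origin": "new", "text": "<placeholder: new feeling-heard item 1>"},
    {"id": "fbh_6", "origin": "new", "text": "<placeholder: new feeling-heard item 2>"},
    {"id": "fbh_7", "origin": "new", "text": "<placeholder: new feeling-heard item 3>"}
  ]
}
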