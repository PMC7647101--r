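{
  "name": "st_binary",
  "groups": [
    {
      "symbol": "s",
      "label": "Ser/Thr (phospho-acceptor)",
      "color": "#D7191C",
      "members": ["S", "T"]
    },
    {
      "symbol": "o",
      "label": "other",
      "color": "#2C7BB6",
      "members": ["A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "V", "W", "Y"]
    }
  ]
}
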