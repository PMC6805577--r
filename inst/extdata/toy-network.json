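{
  "schema_version": "1.0",
  "model": {
    "name": "toy",
    "nodes": [
      {
        "name": "A",
        "states": ["0", "1"]
      },
      {
        "name": "B",
        "states": ["0", "1"]
      },
      {
        "name": "C",
        "states": ["0", "1", "2"]
      }
    ],
    "edges": [
      {
        "from": "A",
        "to": "C",
        "sign": "activate"
      },
      {
        "from": "B",
        "to": "C",
        "sign": "inhibit"
      }
    ]
  },
  "experiments": [
    {
      "name": "ko_B",
      "pins": {
        "B": "0"
      }
    }
  ]
}
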