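{
  "_comment": "Transcription template for the logical rules of the Arabidopsis floral organ fate network (Espinosa-Soto et al. 2004, Plant Cell 16:2923-2939). For each node, fill inputs with its regulator names and rows with its full truth table: each row is {\"when\": [input states, integers, in inputs order], \"then\": next state of the node}, covering every input-state combination exactly once. Load with floral_scaffold(rules_path = ...).",
  "rules": [
    {
      "node": "FT",
      "inputs": [],
      "rows": []
    },
    {
      "node": "EMF1",
      "inputs": [],
      "rows": []
    },
    {
      "node": "SEP",
      "inputs": [],
      "rows": []
    },
    {
      "node": "AP2",
      "inputs": [],
      "rows": []
    },
    {
      "node": "WUS",
      "inputs": [],
      "rows": []
    },
    {
      "node": "UFO",
      "inputs": [],
      "rows": []
    },
    {
      "node": "CLF",
      "inputs": [],
      "rows": []
    },
    {
      "node": "LUG",
      "inputs": [],
      "rows": []
    },
    {
      "node": "LFY",
      "inputs": [],
      "rows": []
    },
    {
      "node": "AP1",
      "inputs": [],
      "rows": []
    },
    {
      "node": "FUL",
      "inputs": [],
      "rows": []
    },
    {
      "node": "TFL1",
      "inputs": [],
      "rows": []
    },
    {
      "node": "AG",
      "inputs": [],
      "rows": []
    },
    {
      "node": "AP3",
      "inputs": [],
      "rows": []
    },
    {
      "node": "PI",
      "inputs": [],
      "rows": []
    }
  ]
}
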