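{
  "species": [
    {
      "name": "X",
      "initial_nM": 0.45,
      "output": true
    },
    {
      "name": "Y",
      "initial_nM": 0.3,
      "output": false
    }
  ],
  "reactions": [
    {
      "id": "autocatalysis",
      "reactants": {
        "X": 2
      },
      "products": {
        "X": 3
      },
      "rate": "k1",
      "modifier": null
    },
    {
      "id": "reverse",
      "reactants": {
        "X": 3
      },
      "products": {
        "X": 2
      },
      "rate": "k2",
      "modifier": null
    },
    {
      "id": "pump",
      "reactants": {},
      "products": {
        "X": 1
      },
      "rate": "k3",
      "modifier": null
    },
    {
      "id": "decay",
      "reactants": {
        "X": 1
      },
      "products": {},
      "rate": "k4",
      "modifier": null
    },
    {
      "id": "shuttle_out",
      "reactants": {
        "X": 1
      },
      "products": {
        "Y": 1
      },
      "rate": "ks1",
      "modifier": null
    },
    {
      "id": "shuttle_back",
      "reactants": {
        "Y": 1
      },
      "products": {
        "X": 1
      },
      "rate": "ks2",
      "modifier": null
    }
  ],
  "parameters": {
    "k1": 6.95,
    "k2": 1,
    "k3": 4.257,
    "k4": 12.385,
    "ks1": 2,
    "ks2": 3
  },
  "input_parameter": "k3"
}
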