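{
  "format": "minnut-model",
  "version": 1,
  "compounds": [
    {
      "id": "A",
      "formula": null,
      "is_class": false,
      "instances": []
    },
    {
      "id": "B",
      "formula": null,
      "is_class": false,
      "instances": []
    },
    {
      "id": "C",
      "formula": null,
      "is_class": false,
      "instances": []
    },
    {
      "id": "D",
      "formula": null,
      "is_class": false,
      "instances": []
    },
    {
      "id": "E",
      "formula": null,
      "is_class": false,
      "instances": []
    },
    {
      "id": "F",
      "formula": null,
      "is_class": false,
      "instances": []
    }
  ],
  "reactions": [
    {
      "id": "R1",
      "reactants": {
        "A": 1,
        "B": 1
      },
      "products": {
        "C": 1,
        "D": 1
      },
      "reversible": false,
      "is_transport": false,
      "is_exchange": false
    },
    {
      "id": "R2",
      "reactants": {
        "C": 1,
        "F": 1
      },
      "products": {
        "B": 1,
        "E": 1
      },
      "reversible": false,
      "is_transport": false,
      "is_exchange": false
    }
  ],
  "transportables": [
    "A",
    "B",
    "F"
  ],
  "biomass": [
    "E"
  ],
  "auxiliaries": []
}
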