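{
  "dimension": 2,
  "reference": "P",
  "contexts": [
    {
      "id": "P",
      "labels": ["P1", "P2"],
      "vectors": [[1.0, 0.0], [0.0, 1.0]]
    },
    {
      "id": "E",
      "labels": ["E1", "E2"],
      "vectors": [[-0.4372, 0.8994], [0.8994, 0.4372]]
    }
  ],
  "state": {
    "frame": "P",
    "coords": [0.2269, 0.9739]
  },
  "metadata": {
    "name": "two-outcome worked example",
    "note": "amplitudes stored at 4-decimal precision; renormalized on load"
  }
}
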