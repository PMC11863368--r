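[
  {
    "name": "L3-L2-L4",
    "transformations": ["L3->L2", "L4->L2", "L3->L4"],
    "signs": [1, -1, -1]
  }
]
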