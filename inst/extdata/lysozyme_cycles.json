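[
  {
    "name": "Ide-Ido-Bzf",
    "transformations": ["Ide->Ido", "Ido->Bzf", "Ide->Bzf"],
    "signs": [1, 1, -1]
  }
]
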