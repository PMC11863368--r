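transformation,ddg_exp_kjmol,bound,sigma_exp_kjmol
L1->L3,1.26,none,
L3->L2,6.69,none,
L3->L4,0.00,none,
L4->L2,6.69,none,
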