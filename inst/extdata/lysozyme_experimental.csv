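transformation,ddg_exp_kjmol,bound,sigma_exp_kjmol
Ben->Phe,10.25,lower,
Eth->Tol,1.00,none,
Tol->Ben,1.38,none,
Ide->Ido,1.00,none,
Ido->Bzf,-2.38,none,
Ide->Bzf,-1.38,none,
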