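name,ki_pred,ki_exp
Amantadine,7.04e-4,8.0e-4
TEA,2.71e-3,4.1e-4
Rimantadine,2.15e-4,8.8e-5
Sotalol,1.09e-4,7.2e-5
Bretylium Tosylate,5.57e-5,3.4e-5
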