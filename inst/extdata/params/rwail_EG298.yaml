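# rWAIL force-field parameters, rigid EG298 variant (ensemble geometry at 298 K).
# Rigid variants carry no intramolecular terms; r_e/theta_e are the constrained geometry.
variant: EG298
q_M: -1.3464
q_H: 0.6732
a: 0.2
A_OO: 2.409e5
alpha: 4.098
C_OO: 610.578
A_4: 78.759
r_c: 2.483
r_e: 0.9706
theta_e: 105.25
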