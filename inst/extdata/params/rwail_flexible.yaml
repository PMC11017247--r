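# rWAIL force-field parameters, flexible variant.
# Units follow the internal convention: kcal/mol, Angstrom, e, degrees.
# A_OO is tabulated in the source as 240.9 x 10^3 kcal/mol and stored here
# pre-multiplied (2.409e5) so parsing is exact.
variant: flexible
q_M: -1.3464        # e
q_H: 0.6732         # e
a: 0.2              # dimensionless M-site factor
A_OO: 2.409e5       # kcal/mol
alpha: 4.098        # 1/Angstrom
C_OO: 610.578       # kcal Angstrom^6 / mol
A_4: 78.759         # kcal Angstrom^4 / mol (applied as kcal/(mol Angstrom^4))
r_c: 2.483          # Angstrom
r_e: 0.9507         # Angstrom
k2: 1263.0          # kcal/(mol Angstrom^2)
k3: -4831.0         # kcal/(mol Angstrom^3)
k4: 10777.0         # kcal/(mol Angstrom^4)
theta_e: 106.66     # degrees
k_theta: 80.81      # kcal/(mol rad^2)
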