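# Physical constants (2019 SI exact values).

E_CHARGE   <- 1.602176634e-19     # elementary charge, C
N_AVOGADRO <- 6.02214076e23       # 1/mol
KB_KCAL    <- 1.987204259e-3      # Boltzmann constant, kcal/mol/K
FARADAY    <- N_AVOGADRO * E_CHARGE   # C/mol
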