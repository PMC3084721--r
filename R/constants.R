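# Canonical internal units: nm (length), nN (force), nN/nm (stiffness).
# Handy identities: 1 nN/nm = 1 N/m and 1 nN/nm^2 = 1 GPa.

.FARADAY <- 96485.33212      # C / mol
.GAS_R <- 8.314462618        # J / (mol K)
.EPS0 <- 8.8541878128e-12    # F / m
.KB_nNnm <- 1.380649e-5      # Boltzmann constant in nN nm / K (1 nN nm = 1e-18 J)
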