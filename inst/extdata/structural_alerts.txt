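# Structural alerts applied to enumerated analogs: reactive, unstable or
# assay-interfering substructures commonly excluded in medicinal-chemistry
# triage. Format: SMARTS pattern, whitespace, alert id.
[$([NX3+](=O)[O-]),$([NX3](=O)=O)]  nitro
[#8]-[#8]               peroxide
[NX3]-[NX3]             hydrazine
[NX3]-[OX2]             hydroxylamine
C(=O)[F,Cl,Br,I]        acyl_halide
[CX3H1](=O)[#6]         aldehyde
N=C=O                   isocyanate
N=[N+]=[N-]             azide
[CX4][Cl,Br,I]          alkyl_halide
[SX2H]                  thiol
[N+X4]                  quaternary_nitrogen
C1OC1                   epoxide
C1NC1                   aziridine
[#6]=[#6]-[CX3](=O)[#6] enone_michael_acceptor
S(=O)(=O)[F,Cl,Br]      sulfonyl_halide
C(=S)                   thiocarbonyl
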