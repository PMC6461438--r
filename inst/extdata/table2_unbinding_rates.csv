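# Fitted unbinding-side rate constants for the eight-repeat consensus TALE
# under different DNA sequences / salt conditions (published point
# estimates, used as inputs). units: s-1 throughout. k1,km1,k2 are not
# constrained by unbinding data and are set to 0 here.
construct,dna,salt,k1,km1,k2,km2,k3,km3
homopolymeric_KCl,Cy5-A15/T15,200 mM KCl,0,0,0,0.66,0.36,0.222
T_anchored_KCl,Cy5-TA14/T14A,200 mM KCl,0,0,0,0.48,0.06,0.31
homopolymeric_MgCl2,Cy5-A15/T15,40 mM MgCl2,0,0,0,1.28,0.32,1.40
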