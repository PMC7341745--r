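elem,sigma,eps,rho_gb,tension
C,3.80,0.09,2.00,0.025
N,3.30,0.17,1.70,-0.060
O,3.00,0.21,1.60,-0.060
S,3.55,0.25,1.90,0.025
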