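label,class,E_B,sigma_B,E_D,delta_E_D,E_rel,delta_E_rel,V_gamma,V_xy
Ox1,Ox,-0.961,0.019,-0.933,0.028,-1.022,-0.089,0.232,0.045
Ox2,Ox,-0.910,0.013,-0.885,0.025,-1.008,-0.123,0.216,0.034
Ox3,Ox,-0.889,0.027,-0.850,0.039,-1.005,-0.155,0.183,0.008
Ox4,Ox,-0.803,0.032,-0.723,0.079,-0.932,-0.209,0.278,0.027
Ox5,Ox,-0.704,0.016,-0.706,-0.002,-0.800,-0.094,0.048,0.003
Hy1,Hy,-0.634,0.021,-0.631,0.003,-0.784,-0.154,0.033,0.001
Hy2,Hy,-0.737,0.041,-0.719,0.019,-0.772,-0.053,0.008,0.003
Hy3,Hy,-0.658,0.027,-0.652,0.005,-0.664,-0.012,0.012,0.003
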