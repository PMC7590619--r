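label,dq_C,dq_O,dq_H,dq_total
Ox1,-0.01,0.08,0.14,0.21
Ox2,-0.00,0.09,0.12,0.21
Ox3,-0.01,0.08,0.13,0.20
Ox4,-0.01,0.10,0.14,0.22
Ox5,-0.02,0.11,0.14,0.23
Hy1,-0.01,0.01,0.11,0.11
Hy2,-0.03,0.01,0.13,0.12
Hy3,0.01,0.00,0.05,0.06
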