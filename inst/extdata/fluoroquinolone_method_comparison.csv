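method,min_cases,sample_size,sensitivity,specificity,ppv,npv,youden
ROR,3,31,1.00,0.90,0.85,1.00,0.90
ROR,4,26,1.00,0.93,0.92,1.00,0.93
ROR,5,20,1.00,0.91,0.90,1.00,0.91
ROR,6,15,1.00,1.00,1.00,1.00,1.00
ROR,7,14,1.00,1.00,1.00,1.00,1.00
ROR,11,8,1.00,1.00,1.00,1.00,1.00
PRR,3,31,1.00,0.90,0.85,1.00,0.90
PRR,4,26,1.00,0.93,0.92,1.00,0.93
PRR,5,20,1.00,0.91,0.90,1.00,0.91
PRR,6,15,1.00,1.00,1.00,1.00,1.00
PRR,7,14,1.00,1.00,1.00,1.00,1.00
PRR,11,8,1.00,1.00,1.00,1.00,1.00
MHRA,3,31,0.91,1.00,1.00,0.95,0.91
MHRA,4,26,0.91,1.00,1.00,0.94,0.91
MHRA,5,20,0.89,1.00,1.00,0.92,0.89
MHRA,6,15,0.88,1.00,1.00,0.88,0.88
MHRA,7,14,0.88,1.00,1.00,0.86,0.88
MHRA,11,8,0.83,1.00,1.00,0.67,0.83
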