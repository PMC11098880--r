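relation,precision,recall,f1
Assisting,0.64,0.88,0.74
Cementing,0.86,0.93,0.89
Cleaning,0.49,0.78,0.60
CloseTo,0.97,0.91,0.94
Cutting,0.36,0.72,0.48
Drilling,0.97,0.97,0.97
Hammering,0.86,0.95,0.90
Holding,0.78,0.90,0.84
LyingOn,1.00,0.98,0.99
Operating,0.85,0.79,0.82
Preparing,0.72,0.90,0.80
Sawing,0.86,0.82,0.84
Suturing,1.00,0.58,0.73
Touching,0.61,0.74,0.67
None,0.98,0.99,0.98
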