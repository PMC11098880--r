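role,method,precision,recall,f1
patient,heuristic,0.99,0.98,0.99
head surgeon,heuristic,0.93,1.00,0.96
assistant surgeon,heuristic,0.74,0.74,0.74
circulating nurse,heuristic,0.65,0.60,0.62
anaesthetist,heuristic,0.61,0.45,0.52
patient,graph-encoder,0.99,0.92,0.96
head surgeon,graph-encoder,0.96,1.00,0.98
assistant surgeon,graph-encoder,0.87,0.96,0.91
circulating nurse,graph-encoder,0.91,0.86,0.88
anaesthetist,graph-encoder,0.72,0.52,0.60
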