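phase,precision,recall,f1
OR Preparation,0.88,1.00,0.94
Patient Roll-In,0.99,0.94,0.97
Patient Preparation,0.96,0.96,0.96
Surgery 1: Implant Placement Preparation,0.95,0.95,0.95
Surgery 2: Implant Placement,0.98,1.00,0.99
Surgery 3: Conclusion,1.00,0.98,0.99
Patient Roll-Out,0.96,0.98,0.97
OR Cleanup,0.98,0.96,0.97
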