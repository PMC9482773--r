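symptom,label,out_strength.18-28,out_strength.29plus,in_strength.18-28,in_strength.29plus,betweenness.18-28,betweenness.29plus,closeness.18-28,closeness.29plus
D1,Anhedonia,1.10,2.62,1.31,2.56,0,8,3.03,4.15
D2,Sad mood,1.82,3.12,1.93,2.84,4,12,3.44,4.46
D3,Sleep problems,0.98,1.57,1.22,1.72,0,0,2.93,3.56
D4,Loss of energy,2.70,2.12,2.05,2.23,8,4,3.43,3.94
D5,Appetite change,1.43,1.14,1.62,1.31,2,0,3.26,2.90
D6,Guilt feelings,1.38,2.56,1.56,2.01,2,8,3.22,3.58
D7,Difficulty in concentration,2.48,2.36,2.48,2.11,4,2,3.94,3.66
D8,Psychomotor problems,2.87,1.52,2.41,1.82,10,0,3.83,3.29
D9,Suicidal ideation,1.02,1.00,1.19,1.39,0,0,2.92,3.31
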