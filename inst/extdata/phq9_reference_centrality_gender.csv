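symptom,label,out_strength.male,out_strength.female,in_strength.male,in_strength.female,betweenness.male,betweenness.female,closeness.male,closeness.female
D1,Anhedonia,1.57,1.60,1.74,1.68,0,2,3.47,3.38
D2,Sad mood,2.58,1.18,2.42,1.31,8,0,3.97,3.10
D3,Sleep problems,1.17,1.00,1.26,1.24,0,0,2.93,3.13
D4,Loss of energy,2.53,3.12,2.35,2.56,10,13,3.90,4.01
D5,Appetite change,1.09,1.49,1.31,1.63,0,0,3.22,3.38
D6,Guilt feelings,1.74,2.40,1.66,2.33,4,7,3.49,3.84
D7,Difficulty in concentration,2.93,2.06,2.70,1.97,8,2,4.27,3.53
D8,Psychomotor problems,2.48,2.79,2.33,2.58,2,6,3.90,4.09
D9,Suicidal ideation,1.03,0.97,1.36,1.30,0,4,3.05,3.15
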