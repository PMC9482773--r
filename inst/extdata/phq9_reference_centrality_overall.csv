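symptom,label,out_strength,in_strength,relative_influence,betweenness,closeness
D4,Loss of energy,3.05,2.61,0.08,12,4.09
D8,Psychomotor problems,2.82,2.60,0.04,6,4.14
D6,Guilt feelings,2.43,2.35,0.02,8,3.88
D7,Difficulty in concentration,2.09,1.95,0.04,2,3.55
D2,Sad mood,1.61,1.66,-0.02,2,3.35
D5,Appetite change,1.48,1.67,-0.06,0,3.43
D1,Anhedonia,1.22,1.317,-0.04,0,3.13
D3,Sleep problems,1.06,1.25,-0.08,0,3.16
D9,Suicidal ideation,0.98,1.324,-0.15,0,3.20
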