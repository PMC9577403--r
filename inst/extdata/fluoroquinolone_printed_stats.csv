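drug,event_pt,cases,mhra_prr,chi2,mhra_signal,prr,prr_low,prr_high,prr_signal,ror,ror_low,ror_high,ror_signal,ic,ic_low,ic_high,bcpnn_strength
levofloxacin,pruritus,57,1.78,19.11,No,1.78,1.39,2.28,Yes,1.99,1.46,2.70,Yes,0.74,0.30,1.18,weak
levofloxacin,rash,56,1.26,2.92,No,1.26,0.98,1.60,No,1.32,0.97,1.79,No,0.29,-0.15,0.74,none
levofloxacin,phlebitis,25,2.08,11.79,Yes,2.08,1.39,3.10,Yes,2.18,1.41,3.38,Yes,0.90,0.28,1.51,weak
levofloxacin,nausea,19,0.96,0.00,No,0.96,0.61,1.50,No,0.96,0.59,1.55,No,-0.06,-0.75,0.63,none
levofloxacin,chest tightness,10,1.08,0.01,No,1.08,0.58,2.04,No,1.09,0.57,2.09,No,0.09,-0.81,0.99,none
levofloxacin,mental disorder,13,8.78,51.66,Yes,8.78,4.47,17.24,Yes,9.17,4.57,18.41,Yes,2.10,1.29,2.90,weak
levofloxacin,vomiting,9,0.95,0.00,No,0.95,0.49,1.84,No,0.95,0.48,1.88,No,-0.08,-1.02,0.87,none
levofloxacin,sleep disorders,7,11.56,32.02,Yes,11.56,4.34,30.80,Yes,11.83,4.37,32.02,Yes,1.95,0.90,2.99,weak
levofloxacin,dizziness,6,0.88,0.01,No,0.88,0.39,1.99,No,0.88,0.38,2.02,No,-0.16,-1.28,0.95,none
levofloxacin,papules,5,0.70,0.35,No,0.70,0.29,1.70,No,0.70,0.28,1.72,No,-0.43,-1.63,0.77,none
levofloxacin,abnormal defecate,5,1.38,0.18,No,1.38,0.55,3.41,No,1.38,0.55,3.49,No,0.32,0.30,1.18,none
levofloxacin,numbness,5,2.97,3.87,No,2.97,1.15,7.70,Yes,3.01,1.14,7.92,Yes,1.02,-0.18,2.22,none
levofloxacin,laboured breathing,4,1.32,0.06,No,1.32,0.48,3.65,No,1.33,0.47,3.71,No,0.27,-1.05,1.58,none
levofloxacin,abdominal discomfort,4,0.91,0.01,No,0.91,0.34,2.49,No,0.91,0.33,2.53,No,-0.12,-1.43,1.19,none
levofloxacin,hallucinations,4,11.89,16.21,Yes,11.89,3.21,44.03,Yes,12.05,3.22,45.13,Yes,1.62,0.30,2.93,weak
levofloxacin,flushing,3,0.91,0.02,No,0.91,0.29,2.90,No,0.91,0.28,2.93,No,-0.12,-1.58,1.34,none
levofloxacin,convulsions,3,8.92,8.44,No,8.92,2.14,37.12,Yes,9.00,2.14,37.88,Yes,1.35,-0.11,2.81,none
levofloxacin,nervousness,3,0.31,4.09,No,0.31,0.10,0.95,No,0.30,0.09,0.94,No,-1.39,-2.85,0.07,none
levofloxacin,eye discomfort,3,1.35,0.03,No,1.35,0.42,4.38,No,1.35,0.41,4.45,No,0.26,-1.20,1.72,none
moxifloxacin,pruritus,19,2.07,10.30,Yes,2.07,1.39,3.09,Yes,2.41,1.42,4.07,Yes,0.93,0.15,1.71,weak
moxifloxacin,phlebitis,11,3.18,14.10,Yes,3.18,1.80,5.60,Yes,3.53,1.84,6.79,Yes,1.36,0.42,2.31,weak
moxifloxacin,rash,9,0.70,1.00,No,0.70,0.38,1.30,No,0.66,0.33,1.34,No,-0.48,-1.49,0.53,none
moxifloxacin,mental disorder,5,11.25,30.45,Yes,11.25,4.39,28.82,Yes,11.94,4.42,32.26,Yes,1.95,0.69,3.21,weak
moxifloxacin,nervousness,5,1.77,0.99,No,1.77,0.75,4.20,No,1.82,0.73,4.58,No,0.62,-0.64,1.88,none
moxifloxacin,sleep disorders,4,20.69,40.31,Yes,20.69,6.63,64.57,Yes,21.74,6.67,70.89,Yes,1.96,0.59,3.32,weak
moxifloxacin,papules,4,1.95,1.00,No,1.95,0.74,5.17,No,2.00,0.72,5.58,No,0.68,-0.69,2.04,none
moxifloxacin,chest tightness,3,1.13,0.01,No,1.13,0.37,3.48,No,1.14,0.35,3.65,No,0.11,-1.40,1.62,none
ciprofloxacin,pruritus,13,2.28,8.96,Yes,2.28,1.42,3.67,Yes,2.75,1.45,5.21,Yes,1.02,0.07,1.97,weak
ciprofloxacin,rash,7,0.88,0.03,No,0.88,0.44,1.75,No,0.86,0.39,1.92,No,-0.19,-1.35,0.97,none
ciprofloxacin,phlebitis,7,3.26,8.88,Yes,3.26,1.62,6.57,Yes,3.64,1.61,8.21,Yes,1.30,0.13,2.46,weak
ciprofloxacin,nausea,4,1.13,0.00,No,1.13,0.44,2.92,No,1.15,0.41,3.21,No,0.12,-1.29,1.52,none
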