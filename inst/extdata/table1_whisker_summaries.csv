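animal_id,sex,year,n_segments,d15N_mean,d15N_sd,d15N_min,d15N_max,d13C_mean,d13C_sd,d13C_min,d13C_max,seac,category
9,F,2014,51,12.94,0.89,10.88,14.21,-21.79,0.46,-22.83,-20.94,1.16,H-Specialist
12,F,2018,61,13.14,0.63,10.88,13.87,-21.41,0.19,-21.98,-20.92,0.29,H-Specialist
57,F,2018,45,13.13,0.83,10.92,14.05,-21.36,0.27,-22.13,-20.82,0.57,H-Specialist
57,F,2023,6,13.16,0.30,12.69,13.63,-21.67,0.23,-21.87,-21.26,0.23,H-Specialist
84,F,2017,26,13.23,0.28,12.64,13.82,-21.68,0.29,-22.49,-21.37,0.26,H-Specialist
128,F,2014,44,12.58,0.28,12.02,13.66,-20.81,0.44,-22.78,-20.37,0.38,H-Specialist
394,F,2013,22,13.34,0.49,12.12,13.92,-21.14,0.30,-21.94,-20.68,0.43,H-Specialist
397,F,2014,77,12.27,0.65,11.01,13.97,-22.11,0.54,-23.30,-21.30,1.00,H-Specialist
397,F,2018,46,12.55,0.41,11.66,13.49,-21.69,0.46,-23.06,-20.97,0.57,H-Specialist
397,F,2019,62,12.47,0.31,11.02,12.97,-21.56,0.59,-23.82,-20.87,0.48,H-Specialist
397,F,2023,49,12.63,0.45,11.64,13.62,-21.60,0.50,-23.03,-20.89,0.73,H-Specialist
406,F,2013,71,13.63,0.57,12.35,15.21,-21.02,0.40,-22.30,-18.71,0.63,H-Specialist
422,F,2013,59,12.26,0.76,10.26,13.43,-21.16,0.40,-22.85,-20.47,0.93,H-Specialist
12,F,2013,47,10.98,0.93,8.60,12.26,-21.29,0.38,-22.73,-20.77,1.15,ML-Specialist
16,F,2014,36,11.67,0.85,10.22,13.41,-22.14,0.32,-22.85,-21.51,0.75,ML-Specialist
37,F,2019,47,11.45,0.56,9.78,12.47,-21.43,0.59,-22.96,-20.56,1.02,ML-Specialist
37,F,2023,35,11.67,0.73,10.17,13.36,-22.02,0.50,-23.26,-21.35,1.18,ML-Specialist
63,F,2014,52,11.08,0.73,8.51,12.56,-21.87,0.55,-22.80,-20.81,1.21,ML-Specialist
84,F,2014,23,11.07,0.89,9.92,12.61,-22.55,0.47,-23.09,-21.59,0.82,ML-Specialist
120,M,2017,18,10.98,0.41,10.06,11.78,-21.54,0.35,-22.60,-21.03,0.48,ML-Specialist
143,F,2018,29,10.31,0.87,8.93,12.53,-22.39,0.27,-23.06,-21.90,0.69,ML-Specialist
144,M,2018,44,10.70,0.97,8.65,12.29,-21.97,0.60,-23.11,-20.92,0.82,ML-Specialist
145,F,2018,64,11.85,0.79,10.17,13.11,-22.91,0.60,-23.69,-21.69,1.20,ML-Specialist
153,F,2019,48,11.60,0.75,10.48,13.38,-21.98,0.58,-22.87,-20.82,0.93,ML-Specialist
158,F,2019,44,11.98,0.59,10.51,12.90,-21.48,0.24,-22.19,-20.98,0.43,ML-Specialist
159,F,2019,43,11.27,0.64,9.70,12.69,-22.16,0.65,-23.20,-21.02,1.19,ML-Specialist
162,F,2019,74,10.07,0.77,8.39,11.81,-23.14,0.56,-24.76,-21.89,1.41,ML-Specialist
18,F,2014,46,10.79,1.25,7.34,12.54,-22.42,0.59,-23.75,-21.46,1.61,Intermediate
36,F,2013,89,11.83,1.04,8.29,13.35,-21.58,0.59,-23.74,-20.67,1.38,Intermediate
37,F,2014,44,11.47,1.03,9.01,12.73,-21.95,0.72,-23.99,-20.97,1.72,Intermediate
71,F,2013,27,12.23,1.23,9.42,13.95,-21.30,0.57,-22.43,-20.52,1.03,Intermediate
128,F,2023,47,12.03,1.12,7.82,15.17,-21.38,0.33,-22.68,-20.93,1.21,Intermediate
140,M,2018,56,8.36,1.07,6.95,11.68,-21.51,0.87,-23.46,-20.36,2.73,Intermediate
141,M,2018,60,10.20,1.38,7.74,12.14,-22.57,0.50,-24.25,-21.96,1.56,Intermediate
142,F,2018,44,10.83,1.23,7.61,12.31,-22.21,1.02,-24.43,-20.70,3.28,Intermediate
156,F,2019,77,10.79,1.19,8.28,13.23,-22.28,0.84,-23.99,-20.87,1.06,Intermediate
157,M,2019,71,10.59,1.02,8.02,11.89,-22.74,0.64,-23.95,-21.30,1.64,Intermediate
160,F,2019,73,10.15,1.16,7.93,11.87,-23.26,0.43,-23.32,-20.83,1.01,Intermediate
161,F,2019,69,10.56,1.22,7.96,14.13,-22.02,0.66,-23.32,-20.83,0.80,Intermediate
406,F,2014,56,12.56,1.06,10.25,14.28,-21.79,0.28,-22.55,-21.22,0.87,Intermediate
12,F,2017,22,11.39,1.58,8.26,14.04,-22.10,0.13,-22.44,-21.88,0.71,Generalist
37,F,2013,36,11.09,1.41,7.54,12.87,-21.65,0.66,-23.07,-21.04,1.85,Generalist
62,F,2023,25,12.18,1.59,9.40,14.38,-21.56,0.38,-22.41,-20.93,1.58,Generalist
111,M,2017,53,9.35,1.53,6.49,12.51,-22.07,0.37,-23.05,-21.52,1.60,Generalist
138,F,2018,30,11.10,1.95,6.96,13.80,-20.74,0.48,-22.50,-19.83,2.90,Generalist
171,F,2020,51,9.35,1.48,7.16,12.82,-22.86,0.53,-23.77,-21.70,1.60,Generalist
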