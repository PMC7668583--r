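method,tpr,n_cp,PTS80,PTS85,PTS90,PTS95,PTS100,PHA80,PHA85,PHA90,PHA95,PHA100,bold_PTS80,bold_PTS85,bold_PTS90,bold_PTS95,bold_PTS100,bold_PHA80,bold_PHA85,bold_PHA90,bold_PHA95,bold_PHA100
REMD,ref,0,50.00,53.47,57.64,63.89,79.17,27.08,30.56,34.72,40.98,58.34,0,0,0,0,0,0,0,0,0,0
REMD,100,6,66.67,68.75,71.53,75.00,87.50,43.06,45.14,47.92,51.39,68.06,1,1,1,1,1,1,1,1,1,1
REMD,100,12,61.11,63.19,65.97,69.44,86.11,37.50,39.58,42.36,45.84,65.28,0,0,0,0,1,0,0,0,0,1
REMD,100,24,71.53,73.61,75.00,77.08,88.89,47.92,49.30,51.39,53.47,68.75,1,1,1,1,1,1,1,1,1,1
REMD,100,36,71.53,73.61,75.00,77.08,88.89,47.92,50.00,51.39,54.16,70.83,1,1,1,1,1,1,1,1,1,1
REMD,100,48,72.22,73.61,75.00,77.08,87.50,48.61,50.00,51.39,53.47,68.06,1,1,1,1,1,1,1,1,1,1
REMD,75,12,47.92,50.70,54.17,59.02,87.50,24.30,27.08,30.56,34.72,65.97,0,0,0,0,1,0,0,0,0,1
REMD,75,24,49.30,54.86,59.02,70.14,84.72,25.00,30.56,34.72,45.83,64.58,0,0,0,0,1,0,0,0,0,1
REMD,75,36,68.06,71.53,74.31,77.08,88.89,43.75,47.22,50.00,53.47,70.83,1,1,1,1,1,1,1,1,1,1
REMD,75,48,62.50,65.97,69.44,73.61,85.42,38.89,42.36,45.83,49.30,63.89,0,0,1,1,1,0,0,0,0,1
REMD,50,12,34.03,38.89,44.44,50.70,79.17,13.20,17.36,21.53,27.08,55.56,0,0,0,0,1,0,0,0,0,0
REMD,50,24,31.25,34.03,36.80,44.45,73.61,10.42,11.81,14.58,22.22,50.00,0,0,0,0,0,0,0,0,0,0
REMD,50,36,28.47,31.94,36.11,40.28,70.83,9.03,11.11,14.58,18.06,49.30,0,0,0,0,0,0,0,0,0,0
REMD,50,48,28.47,30.56,34.03,36.81,59.72,9.03,9.72,12.50,15.28,36.11,0,0,0,0,0,0,0,0,0,0
MD,ref,0,25.70,27.08,28.47,35.42,50.00,9.03,9.72,11.11,13.19,26.39,0,0,0,0,0,0,0,0,0,0
MD,100,24,41.66,42.36,43.06,44.44,57.64,17.36,18.06,18.75,20.14,32.64,0,0,0,0,0,0,0,0,0,0
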