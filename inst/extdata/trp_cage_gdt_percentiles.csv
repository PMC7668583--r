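method,tpr,n_cp,PTS80,PTS85,PTS90,PTS95,PTS100,PHA80,PHA85,PHA90,PHA95,PHA100,bold_PTS80,bold_PTS85,bold_PTS90,bold_PTS95,bold_PTS100,bold_PHA80,bold_PHA85,bold_PHA90,bold_PHA95,bold_PHA100
REMD,ref,0,53.75,88.75,93.75,96.25,100.00,30.00,67.50,76.25,81.25,98.75,0,0,0,0,0,0,0,0,0,0
REMD,100,6,96.25,96.25,97.50,97.50,100.00,80.00,81.25,82.50,85.00,96.25,1,1,1,0,1,1,0,0,0,0
REMD,100,12,96.25,97.50,97.50,98.75,100.00,81.25,82.50,83.75,86.25,97.50,1,1,1,1,1,1,0,0,0,0
REMD,100,24,97.50,97.50,97.50,98.75,100.00,82.50,83.75,85.00,86.25,97.50,1,1,1,1,1,1,1,0,0,0
REMD,100,36,97.50,97.50,97.50,98.75,100.00,82.50,83.75,85.00,86.25,97.50,1,1,1,1,1,1,1,0,0,0
REMD,100,48,97.50,97.50,98.75,98.75,100.00,82.50,83.75,85.00,86.25,97.50,1,1,1,1,1,1,1,0,0,0
REMD,75,12,95.00,96.25,97.50,97.50,100.00,78.75,80.00,82.50,85.00,98.75,1,1,1,0,1,1,0,0,0,1
REMD,75,24,95.00,96.25,96.25,97.50,100.00,77.50,80.00,81.25,83.75,96.25,1,1,0,0,1,1,0,0,0,0
REMD,75,36,96.25,96.25,97.50,97.50,100.00,80.00,81.25,82.50,85.00,96.25,1,1,1,0,1,1,0,0,0,0
REMD,75,48,96.25,96.25,97.50,98.75,100.00,80.00,81.25,83.75,85.00,97.50,1,1,1,1,1,1,0,0,0,0
REMD,50,12,41.25,47.50,85.00,95.00,100.00,16.25,23.75,62.50,77.50,96.25,0,0,0,0,1,0,0,0,0,0
REMD,50,24,40.00,42.50,47.50,91.25,100.00,17.50,20.00,23.75,71.25,96.25,0,0,0,0,1,0,0,0,0,0
REMD,50,36,36.25,38.75,41.25,43.75,95.00,15.00,17.50,20.00,22.50,82.50,0,0,0,0,0,0,0,0,0,0
REMD,50,48,37.50,38.75,42.50,46.25,93.75,15.00,17.50,18.75,23.75,76.25,0,0,0,0,0,0,0,0,0,0
MD,ref,0,33.75,36.25,40.00,43.75,56.25,11.25,13.75,16.25,20.00,32.50,0,0,0,0,0,0,0,0,0,0
MD,100,12,53.75,55.00,56.25,57.50,68.75,28.75,30.00,31.25,33.75,45.00,0,0,0,0,0,0,0,0,0,0
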