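# Symmetric typical-path human whole-lung morphometry after Yeh & Schum (1980).
# One row per generation; generation g stands for 2^(g-1) identical airways.
# Generations 1-17 tracheobronchial (trachea = generation 1), 18-24 pulmonary.
# branching_angle_deg is measured from the parent axis, gravity_angle_deg from
# the gravity vector for the upright posture.
generation,region,length_cm,diameter_cm,branching_angle_deg,gravity_angle_deg
1,TB,10.0,2.01,0,0
2,TB,4.36,1.56,33,20
3,TB,1.78,1.13,34,31
4,TB,0.965,0.827,22,43
5,TB,0.995,0.651,20,39
6,TB,1.01,0.574,18,39
7,TB,0.890,0.435,19,40
8,TB,0.962,0.373,22,36
9,TB,0.867,0.322,28,39
10,TB,0.667,0.257,22,45
11,TB,0.556,0.198,33,43
12,TB,0.446,0.156,34,45
13,TB,0.359,0.118,37,45
14,TB,0.275,0.092,39,60
15,TB,0.212,0.073,39,60
16,TB,0.168,0.060,51,60
17,TB,0.134,0.054,45,60
18,PUL,0.120,0.050,45,60
19,PUL,0.092,0.047,45,60
20,PUL,0.080,0.045,45,60
21,PUL,0.070,0.044,45,60
22,PUL,0.063,0.044,45,60
23,PUL,0.057,0.043,45,60
24,PUL,0.053,0.043,45,60
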