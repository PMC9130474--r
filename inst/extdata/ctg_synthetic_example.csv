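LB,AC,FM,UC,ASTV,mSTV,ALTV,mLTV,DL,DS,DP,DR,Width,Min,Max,Nmax,Nzeros,Mode,Mean,Median,Variance,Tendency,NSP
133.293,8,5,10,34.581,1.351,7.135,9.473,0,0,1,0,94.949,124.522,142.648,6,0,126.458,135.022,143.162,25.907,0.69,1
149.151,1,13,3,43.877,1.314,40.438,9.536,2,0,0,0,97.26,112.101,165.819,3,1,134.61,138.253,151.55,22.603,0.284,1
136.609,3,24,6,48.275,1.127,8.384,9.884,1,0,0,0,102.017,127.207,173.594,2,0,136.893,142.33,155.872,17.109,-0.086,1
119.349,3,15,5,33.711,1.243,-11.757,15.563,2,0,1,0,49.896,103.06,174.561,0,0,146.287,137.463,134.851,73.035,0.927,1
125.131,6,3,3,46.719,2.591,-0.636,8.124,3,0,0,0,126.941,109.026,158.569,3,1,135.823,125.473,133.494,25.908,1.269,1
127.543,4,25,5,44.797,1.568,17.767,9.672,1,0,0,0,56.667,87.714,165.431,2,1,112.98,147.823,158.83,15.043,0.282,1
144.241,5,23,9,37.2,1.672,3.99,13.674,3,0,0,0,66.298,113.318,181.303,3,0,138.811,157.602,114.649,-43.698,0.637,1
135.598,4,16,6,40.849,1.746,1.01,13.217,0,0,0,0,119.142,88.861,137.784,1,0,155.433,146.455,131.884,-20.132,0.242,1
136.008,4,12,5,39.557,2.339,4.497,13.581,0,0,1,0,115.293,68.748,149.929,8,1,155.491,109.733,144.404,17.058,0.91,1
133.107,8,0,4,67.67,1.29,11.448,6.69,3,0,0,0,31.85,102.816,169.767,4,0,129.743,153.194,115.351,24.157,-0.394,1
126.442,3,28,0,30.363,1.004,35.576,17.01,2,0,0,0,39.443,142.809,155.994,7,1,119.879,134.271,141.915,25.922,1.693,1
149.869,9,0,8,25.752,2.605,8.583,9.267,0,0,0,0,22.467,117.62,188.66,0,0,171.955,141.824,164.29,39.538,-0.062,1
136.979,0,41,1,40.491,1.335,27.293,16.467,0,0,0,0,76.365,125.636,176.119,3,1,137.889,143.086,137.943,14.146,-0.575,1
112.334,6,31,7,44.036,1.166,20.092,3.596,1,0,0,0,75.769,107.895,165.299,2,1,138.733,133.743,134.102,49.365,0.089,1
139.014,4,4,10,45.675,0.858,8.182,9.084,2,0,0,0,82.744,86.612,136.86,1,1,145.467,134.022,144.649,-4.038,0.388,1
127.272,5,0,1,34.041,0.829,-14.526,14,1,0,0,0,89.326,95.551,164.47,8,0,119.017,148.249,134.093,-11.211,1.274,1
121.322,5,0,7,26.177,1.256,1.662,6.139,2,0,1,0,48.934,93.989,158.305,0,1,130.533,144.251,149.388,-11.725,0.847,1
129.82,2,12,4,56.421,1.971,2.162,5.989,2,0,0,0,35.221,89.689,162.158,5,1,119.974,147.873,150.662,37.557,0.385,1
121.74,3,4,1,35.455,2.266,10.754,5.246,4,0,0,0,105.937,115.492,142.732,6,2,130.99,165.978,138.038,16.927,-0.534,1
124.711,1,3,1,28.748,2.025,30.803,4.79,1,0,1,0,96.287,73.658,172.976,4,0,141.545,143.637,121.526,38.745,-0.22,1
125.75,1,0,1,36.928,1.382,46.689,7.251,1,0,0,0,17.179,119.06,145.299,2,0,122.259,137.696,119.545,12.307,0.202,1
115.133,5,7,4,37.437,1.636,34.761,10.325,0,0,0,0,66.67,119.011,159.928,6,0,147.67,106.262,129.698,4.203,1.832,1
140.378,5,0,1,54.429,1.177,7.87,0.943,1,0,1,0,38.642,73.63,170.866,4,0,143.761,169.992,149.163,9.791,-0.816,1
133.534,4,0,7,41.102,1.17,-18.104,9.848,0,0,0,0,-2.476,114.069,149.897,1,0,128.245,128.725,110.585,-27.315,0.979,1
120.619,7,2,10,49.803,2.131,3.78,13.947,0,0,1,0,75.254,153.465,174.494,1,1,142.942,165.872,111.591,-10.24,-0.016,2
160.538,6,74,0,68.509,-0.209,11.427,11.15,4,0,0,0,67.228,47.741,140.303,9,1,119.725,109.87,128.847,-17.051,1.3,2
136.265,3,0,7,42.788,2.773,23.52,14.205,3,0,0,0,66.592,118.588,113.424,2,0,153.794,155,143.522,45.358,-0.384,2
145.049,0,69,3,70.779,0.346,25.4,6.027,1,0,0,0,77.565,42.792,172.369,0,0,107.233,103.574,125.21,4.067,0.386,2
156.951,3,36,2,76.23,0.529,20.949,-3.907,3,0,0,0,100.886,84.436,179.13,5,1,108.783,111.649,150.414,38.736,-0.36,2
140.781,2,7,2,28.36,1.157,-12.324,6.594,1,0,0,0,77.196,105.496,158.855,5,0,138.873,137.781,142.667,56.912,0.842,2
140.216,2,16,5,22.96,1.255,23.594,7.592,0,0,0,0,48.425,136.342,173.074,1,0,158.739,132.58,135.611,14.206,1.19,2
154.886,3,65,0,100.964,-0.39,2.855,5.814,5,0,0,0,44.282,27.903,143.194,0,0,124.626,103.435,149.464,26.097,1.47,2
153.539,0,62,2,82.809,0.29,12.797,2.577,5,0,1,0,65.387,58.871,161.711,4,0,120.847,118.167,143.437,-24.777,0.779,3
147.381,0,50,0,58.733,0.651,11.193,-2.035,4,0,1,0,80.851,48.408,129.053,7,0,106.265,102.381,131.757,-1.467,1.406,3
144.94,1,47,3,67.055,0.595,16.851,9.738,0,0,0,0,33.611,55.66,185.261,6,0,114.852,78.51,141.236,20.405,1.048,3
144.195,0,45,0,59.589,-0.069,10.395,6.646,8,0,1,0,63.549,46.149,197.478,3,0,115.243,102.453,147.065,26.477,0.221,3
141.053,0,62,4,103.585,-0.073,-16.68,3.95,4,0,0,0,103.854,41.655,183.332,2,1,96.458,112.017,142.988,0.015,0.586,3
145.921,1,46,0,92.061,0.099,21.784,7.872,5,0,0,0,66.21,72.732,163.508,5,1,87.532,113.014,128.788,86.121,-0.283,3
135.346,0,53,0,71.553,1.298,16.176,-2.355,4,0,1,0,45.555,36.073,163.4,4,0,118.344,113.015,149.973,7.54,0.189,3
169.69,2,56,9,82.062,-0.282,5.75,5.643,6,0,0,0,60.342,92.649,136.711,6,0,90.119,83.003,154.141,20.606,1.033,3
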