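tree_id,plot_label,x_m,y_m,crown_area,species
t001,SYN-1,34.61,71.03,35.527,CARAPA
t002,SYN-1,30.48,83.19,62.828,CARAPA
t003,SYN-1,73.23,34.23,5.658,CARAPA
t004,SYN-1,74.48,79.24,43.087,CARAPA
t005,SYN-1,46.63,53.09,,CARAPA
t006,SYN-1,12.81,38.62,49.382,OTHER
t007,SYN-1,51.05,22.06,13.164,PENTACL
t008,SYN-1,31.17,13.85,30.932,OTHER
t009,SYN-1,9.21,11.37,37.623,CARAPA
t010,SYN-1,79.89,52.63,52.406,CARAPA
t011,SYN-1,6.96,0.04,23.744,CARAPA
t012,SYN-1,99.4,48.68,20.43,PENTACL
t013,SYN-1,95.83,65.65,17.87,CARAPA
t014,SYN-1,32.27,72.07,45.971,CARAPA
t015,SYN-1,93.87,51.77,11.557,PENTACL
t016,SYN-1,4,10.38,17.26,CARAPA
t017,SYN-1,87.64,45.52,,CARAPA
t018,SYN-1,35.89,48.65,19.117,OTHER
t019,SYN-1,31.56,24.86,13.993,CARAPA
t020,SYN-1,62.22,81.41,85.994,CARAPA
t021,SYN-1,20.73,91.37,1.921,PENTACL
t022,SYN-1,21.3,83.98,22.83,PENTACL
t023,SYN-1,54.37,18.13,10.543,OTHER
t024,SYN-1,60.24,52.06,24.723,PENTACL
t025,SYN-1,18.64,96.4,73.912,PENTACL
t026,SYN-1,85.69,37.06,15.531,CARAPA
t027,SYN-1,55.62,39.87,9.637,CARAPA
t028,SYN-1,0.93,66.51,26.596,CARAPA
t029,SYN-1,58.9,52.61,61.977,CARAPA
t030,SYN-1,22.14,28.92,18.351,PENTACL
t031,SYN-1,39.86,36.86,59.906,PENTACL
t032,SYN-1,86,93.94,28.131,PENTACL
t033,SYN-1,95.66,15.25,50.893,OTHER
t034,SYN-1,8.58,96.63,17.158,OTHER
t035,SYN-1,93.67,83.64,1.428,CARAPA
t036,SYN-1,66.99,9.07,123.191,OTHER
t037,SYN-1,96.17,15.02,13.049,PENTACL
t038,SYN-1,19.21,16.32,47.639,PENTACL
t039,SYN-1,29.41,34.34,14.065,PENTACL
t040,SYN-1,56.61,73.31,,CARAPA
t041,SYN-1,4.46,86.13,7.495,OTHER
t042,SYN-1,14.74,42.45,26.507,OTHER
t043,SYN-1,75.96,51.63,97.885,CARAPA
t044,SYN-1,96.34,36.13,18.189,PENTACL
t045,SYN-1,19.86,85.08,48.253,PENTACL
t046,SYN-1,57.46,83.01,40.66,OTHER
t047,SYN-1,86.14,98.72,9.361,CARAPA
t048,SYN-1,60.68,27.47,7.938,PENTACL
t049,SYN-2,9.63,42.16,8.144,OTHER
t050,SYN-2,55.76,7.62,24.206,PENTACL
t051,SYN-2,35.5,49.99,30.719,PENTACL
t052,SYN-2,1.14,37.27,29.889,CARAPA
t053,SYN-2,47.16,59.74,5.104,CARAPA
t054,SYN-2,40.74,51.43,22.449,OTHER
t055,SYN-2,5.71,56.17,75.807,CARAPA
t056,SYN-2,22.39,56.41,38.215,CARAPA
t057,SYN-2,57.62,1.66,102.108,CARAPA
t058,SYN-2,14.24,42.99,68.986,PENTACL
t059,SYN-2,6.5,7.67,35.27,PENTACL
t060,SYN-2,17.16,34.28,50.929,CARAPA
t061,SYN-2,52.74,34.5,4.809,CARAPA
t062,SYN-2,11.14,52.71,12.337,OTHER
t063,SYN-2,51.89,36.08,20.267,CARAPA
t064,SYN-2,46.27,8.8,5.255,CARAPA
t065,SYN-2,1.32,10.47,10.752,PENTACL
t066,SYN-2,7.63,19.33,56.823,OTHER
t067,SYN-2,31.87,27.41,28.075,OTHER
t068,SYN-2,36.6,16.79,43.44,OTHER
t069,SYN-2,2.59,44.22,8.974,PENTACL
t070,SYN-2,50.41,23.62,2.729,CARAPA
t071,SYN-2,53.49,22.06,25.245,OTHER
t072,SYN-2,46.97,57.34,36.86,OTHER
t073,SYN-2,40.1,39.94,177.636,CARAPA
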