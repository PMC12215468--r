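# Per-scan signed surface-distance summaries (mm) for paired weight-bearing
# cone-beam CT vs multidetector CT knee bone models, as published:
# 4 patient scans, 10 single-leg cadaver scans, 10 bilateral-leg cadaver scans;
# columns: mean, sd and mean +/- 1.96 sd interval of the per-vertex signed
# surface distance (A = cone-beam model measured against B = MDCT model).
dataset,subject,bone,mean_mm,sd_mm,upper_mm,lower_mm
patient,1,femur,0.01,0.36,0.72,-0.69
patient,1,tibia,0.07,0.38,0.81,-0.68
patient,1,fibula,-0.35,0.83,1.28,-1.98
patient,1,patella,0.005,0.33,0.65,-0.64
patient,2,femur,0.11,0.31,0.72,-0.49
patient,2,tibia,0.05,0.5,1.03,-0.93
patient,2,fibula,0.07,0.44,0.93,-0.79
patient,2,patella,-0.07,0.45,0.81,-0.95
patient,3,femur,0.003,0.38,0.75,-0.74
patient,3,tibia,0.003,0.38,0.75,-0.74
patient,3,fibula,-0.12,0.54,0.94,-1.18
patient,3,patella,-0.07,0.55,1.01,-1.15
patient,4,femur,-0.1,0.6,1.08,-1.28
patient,4,tibia,-0.05,0.45,0.83,-0.93
patient,4,fibula,0.09,0.26,0.6,-0.42
patient,4,patella,-0.01,0.33,0.64,-0.66
cadaver_single,1,femur,-0.05,0.44,0.81,-0.9
cadaver_single,1,tibia,-0.17,0.36,0.53,-0.88
cadaver_single,1,fibula,-0.16,0.4,0.63,-0.94
cadaver_single,1,patella,0.03,0.34,0.7,-0.64
cadaver_single,2,femur,0.05,1.24,2.47,-2.38
cadaver_single,2,tibia,-0.23,0.44,0.63,-1.09
cadaver_single,2,fibula,-0.11,0.32,0.51,-0.73
cadaver_single,2,patella,-0.1,0.28,0.46,-0.66
cadaver_single,3,femur,0.05,0.43,0.9,-0.8
cadaver_single,3,tibia,0.04,0.37,0.77,-0.69
cadaver_single,3,fibula,-0.07,0.34,0.6,-0.74
cadaver_single,3,patella,0.01,0.31,0.62,-0.6
cadaver_single,4,femur,0.03,0.56,1.13,-1.07
cadaver_single,4,tibia,-0.04,0.38,0.7,-0.78
cadaver_single,4,fibula,-0.11,0.3,0.49,-0.71
cadaver_single,4,patella,-0.09,0.31,0.51,-0.69
cadaver_single,5,femur,0.01,0.45,0.89,-0.86
cadaver_single,5,tibia,-0.02,0.4,0.76,-0.8
cadaver_single,5,fibula,-0.06,0.34,0.61,-0.73
cadaver_single,5,patella,0.1,0.41,0.9,-0.7
cadaver_single,6,femur,-0.27,0.36,0.42,-0.97
cadaver_single,6,tibia,-0.16,0.3,0.44,-0.76
cadaver_single,6,fibula,-0.18,0.26,0.33,-0.7
cadaver_single,6,patella,-0.16,0.31,0.46,-0.78
cadaver_single,7,femur,-0.05,0.54,1.01,-1.1
cadaver_single,7,tibia,0.05,0.41,0.86,-0.75
cadaver_single,7,fibula,-0.16,0.44,0.71,-1.03
cadaver_single,7,patella,-0.02,0.4,0.76,-0.8
cadaver_single,8,femur,0.11,1.09,2.24,-2.03
cadaver_single,8,tibia,-0.06,0.41,0.74,-0.85
cadaver_single,8,fibula,-0.07,0.33,0.57,-0.71
cadaver_single,8,patella,-0.02,0.38,0.72,-0.77
cadaver_single,9,femur,-0.18,0.38,0.55,-0.92
cadaver_single,9,tibia,-0.26,0.39,0.5,-1.02
cadaver_single,9,fibula,-0.28,0.36,0.43,-0.99
cadaver_single,9,patella,-0.2,0.34,0.47,-0.87
cadaver_single,10,femur,-0.04,0.37,0.68,-0.76
cadaver_single,10,tibia,-0.06,0.39,0.72,-0.83
cadaver_single,10,fibula,-0.08,0.41,0.72,-0.88
cadaver_single,10,patella,0.06,0.32,0.69,-0.57
cadaver_bilateral,1,femur,0.15,0.99,2.08,-1.78
cadaver_bilateral,1,tibia,-0.08,0.57,1.04,-1.2
cadaver_bilateral,1,fibula,-0.06,0.5,0.92,-1.03
cadaver_bilateral,1,patella,-0.09,0.39,0.67,-0.86
cadaver_bilateral,2,femur,0.04,0.73,1.47,-1.38
cadaver_bilateral,2,tibia,-0.17,0.43,0.67,-1
cadaver_bilateral,2,fibula,-0.04,0.36,0.66,-0.74
cadaver_bilateral,2,patella,-0.06,0.32,0.58,-0.69
cadaver_bilateral,3,femur,0.19,1.17,2.48,-2.1
cadaver_bilateral,3,tibia,0.05,0.38,0.79,-0.7
cadaver_bilateral,3,fibula,-0.04,0.46,0.86,-0.94
cadaver_bilateral,3,patella,-0.09,0.38,0.65,-0.83
cadaver_bilateral,4,femur,0.11,1.05,2.18,-1.95
cadaver_bilateral,4,tibia,0.05,0.47,0.96,-0.86
cadaver_bilateral,4,fibula,-0.02,0.46,0.88,-0.93
cadaver_bilateral,4,patella,-0.07,0.32,0.56,-0.69
cadaver_bilateral,5,femur,-0.05,1.01,1.93,-2.02
cadaver_bilateral,5,tibia,-0.1,0.38,0.65,-0.85
cadaver_bilateral,5,fibula,-0.15,0.28,0.41,-0.7
cadaver_bilateral,5,patella,-0.04,0.47,0.89,-0.96
cadaver_bilateral,6,femur,-0.21,0.56,0.88,-1.3
cadaver_bilateral,6,tibia,-0.08,0.37,0.65,-0.82
cadaver_bilateral,6,fibula,-0.2,0.3,0.39,-0.79
cadaver_bilateral,6,patella,-0.12,0.39,0.64,-0.87
cadaver_bilateral,7,femur,0.03,1.14,2.26,-2.21
cadaver_bilateral,7,tibia,-0.24,0.32,0.39,-0.87
cadaver_bilateral,7,fibula,-0.19,0.3,0.4,-0.78
cadaver_bilateral,7,patella,-0.05,0.28,0.5,-0.6
cadaver_bilateral,8,femur,-0.22,0.72,1.18,-1.62
cadaver_bilateral,8,tibia,-0.27,0.48,0.68,-1.22
cadaver_bilateral,8,fibula,-0.13,0.32,0.49,-0.76
cadaver_bilateral,8,patella,-0.04,0.32,0.58,-0.66
cadaver_bilateral,9,femur,-0.3,0.89,1.44,-2.04
cadaver_bilateral,9,tibia,-0.23,0.41,0.58,-1.04
cadaver_bilateral,9,fibula,-0.22,0.36,0.48,-0.92
cadaver_bilateral,9,patella,-0.1,0.37,0.62,-0.83
cadaver_bilateral,10,femur,-0.25,0.79,1.29,-1.79
cadaver_bilateral,10,tibia,-0.2,0.34,0.47,-0.87
cadaver_bilateral,10,fibula,-0.14,0.32,0.49,-0.77
cadaver_bilateral,10,patella,0.01,0.28,0.56,-0.54
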