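description,mean_nh,sd_nh,mean_nl,sd_nl,mean_ph,sd_ph,mean_pl,sd_pl
valence,-0.92,0.24,-0.83,0.25,0.78,0.16,0.96,0.16
arousal,0.37,0.11,-0.24,0.27,0.25,0.18,-0.38,0.29
hue,0.35,0.12,0.26,0.11,0.41,0.18,0.34,0.24
saturation,0.25,0.08,0.27,0.16,0.33,0.16,0.35,0.18
value,0.47,0.09,0.52,0.07,0.60,0.12,0.54,0.14
amp_left,10.00,3.38,14.75,3.26,13.78,2.79,11.85,2.86
amp_right,10.44,3.55,14.76,3.26,13.73,2.80,11.31,2.60
freq_left,379.22,361.05,241.26,137.93,465.58,697.45,1161.76,1441.87
freq_right,454.71,372.69,241.66,137.70,491.21,687.18,1170.00,1435.29
motion_1,122108.01,54831.82,36616.89,34589.29,91659.27,44101.18,32263.66,31748.91
motion_2,53812.82,22459.94,17790.62,14413.37,43402.15,20830.68,15407.53,14798.81
motion_3,38860.56,15262.57,14337.7,10537.67,30810.13,14032,12256.57,11724.12
motion_4,24938.01,9014.75,10388.2,6386.2,18924.16,8638.21,8335.32,7803.32
motion_5,15024.27,4520.56,6986.16,3533.85,12377.26,5407.69,5579.42,4900.99
motion_6,7305.06,2337.75,3863.75,1697.84,6830.85,3381.41,2720.06,2723.28
motion_7,2597.47,846.05,1308.79,695.17,2668.86,2197.91,989.22,911.23
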