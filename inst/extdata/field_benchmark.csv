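type,ratio,method,mae,rmse,r2
fully,1.0,CSRNet,192.89,246.03,0.3816
fully,1.0,CANNet,199.73,252.57,0.4547
fully,1.0,MobileCount,45.31,57.32,0.9591
fully,1.0,TasselNetV2+,41.03,55.00,0.9647
semi,0.1,L2R,83.61,115.79,0.8537
semi,0.1,IRAST,60.50,88.00,0.9222
semi,0.1,PAL,90.97,121.59,0.8167
semi,0.1,S2FPR,NA,NA,NA
semi,0.1,ours,30.57,40.21,0.9787
semi,0.2,L2R,72.47,89.86,0.9021
semi,0.2,IRAST,51.52,72.02,0.9389
semi,0.2,PAL,80.37,102.33,0.8503
semi,0.2,S2FPR,102.76,121.77,0.7829
semi,0.2,ours,28.01,37.65,0.9817
semi,0.3,L2R,63.81,89.64,0.9148
semi,0.3,IRAST,41.81,60.84,0.9508
semi,0.3,PAL,83.16,106.32,0.8464
semi,0.3,S2FPR,108.42,138.50,0.7753
semi,0.3,ours,27.58,37.22,0.9823
semi,0.4,L2R,67.67,94.98,0.8996
semi,0.4,IRAST,44.43,64.51,0.9509
semi,0.4,PAL,85.62,118.13,0.8115
semi,0.4,S2FPR,95.97,135.45,0.8112
semi,0.4,ours,27.12,36.12,0.9829
semi,0.5,L2R,60.71,87.99,0.9257
semi,0.5,IRAST,39.11,58.66,0.9612
semi,0.5,PAL,76.04,92.91,0.8868
semi,0.5,S2FPR,90.74,126.71,0.8172
semi,0.5,ours,26.47,36.32,0.9839
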