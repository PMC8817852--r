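record,face,eye_closing_rate,yawn,deep_yawn,yaw,yaw_frames,pitch,pitch_frames,roll,roll_frames,alert
1,1,0.23,0,0,-8.19,6,-3.48,0,-1.67,0,Y
2,1,0.03,0,1,2.00,0,1.78,0,0.73,0,Y
3,0,NA,NA,NA,NA,NA,NA,NA,NA,NA,N
4,1,0.11,2,0,19.13,7,-6.32,0,4.05,0,Y
5,1,0.06,1,0,32.60,206,-19.13,35,1.70,0,Y
6,1,0.09,0,0,6.57,0,-3.43,0,-3.70,0,N
7,1,0.32,0,2,18.49,17,-13.46,0,-20.95,72,Y
8,1,0.14,1,0,4.36,0,-20.31,137,-0.59,0,Y
9,1,0.16,1,0,23.72,12,-9.98,0,8.31,0,N
10,1,0.05,0,0,2.95,0,-5.93,0,-23.53,139,Y
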