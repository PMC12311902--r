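allele,class,gene,r_prime
A*01:01,I,A,-0.24
A*02:01,I,A,0.252
A*02:05,I,A,-0.421
A*03:01,I,A,0.779
A*11:01,I,A,-0.614
A*23:01,I,A,-0.722
A*24:02,I,A,0.282
A*25:01,I,A,0.082
A*26:01,I,A,-0.59
A*29:01,I,A,-0.015
A*29:02,I,A,-0.371
A*30:01,I,A,-0.088
A*30:02,I,A,-0.379
A*31:01,I,A,0.982
A*32:01,I,A,-0.674
A*33:01,I,A,-0.422
A*33:03,I,A,-0.607
A*36:01,I,A,-0.435
A*68:01,I,A,0.087
A*68:02,I,A,-0.112
B*07:02,I,B,1.013
B*08:01,I,B,0.42
B*13:02,I,B,0.115
B*14:01,I,B,-0.404
B*14:02,I,B,-0.448
B*15:01,I,B,1.037
B*15:17,I,B,-0.218
B*15:18,I,B,-0.495
B*18:01,I,B,-0.855
B*27:02,I,B,-0.108
B*27:05,I,B,0.502
B*35:01,I,B,-0.101
B*35:02,I,B,-0.572
B*35:03,I,B,-0.698
B*35:08,I,B,-0.773
B*37:01,I,B,1.181
B*38:01,I,B,-1.095
B*39:01,I,B,-0.174
B*39:06,I,B,-0.217
B*40:01,I,B,0.957
B*40:02,I,B,0.256
B*41:01,I,B,-0.362
B*41:02,I,B,-0.734
B*44:02,I,B,0.108
B*44:03,I,B,-0.365
B*44:05,I,B,-0.512
B*45:01,I,B,-0.299
B*47:01,I,B,-0.316
B*49:01,I,B,-0.898
B*50:01,I,B,-0.649
B*51:01,I,B,-0.799
B*52:01,I,B,-0.389
B*55:01,I,B,0.494
B*56:01,I,B,0.232
B*57:01,I,B,-0.139
B*58:01,I,B,-0.432
C*01:02,I,C,0.102
C*03:03,I,C,0.542
C*04:01,I,C,-0.775
C*05:01,I,C,0.181
C*06:02,I,C,-0.022
C*07:01,I,C,0.118
C*07:02,I,C,1.259
C*07:04,I,C,-0.245
C*12:02,I,C,-0.514
C*12:03,I,C,-0.732
C*14:02,I,C,-0.662
C*15:02,I,C,-0.554
C*16:01,I,C,-0.116
DPB1*01:01,II,DPB1,0.885
DPB1*02:01,II,DPB1,-0.826
DPB1*02:02,II,DPB1,-0.4
DPB1*03:01,II,DPB1,0.109
DPB1*04:01,II,DPB1,0.627
DPB1*04:02,II,DPB1,0.003
DPB1*05:01,II,DPB1,0.268
DPB1*06:01,II,DPB1,-0.135
DPB1*09:01,II,DPB1,-0.227
DPB1*10:01,II,DPB1,-0.924
DPB1*11:01,II,DPB1,0.008
DPB1*13:01,II,DPB1,-0.777
DPB1*14:01,II,DPB1,-0.747
DPB1*17:01,II,DPB1,-0.275
DPB1*19:01,II,DPB1,0.204
DQB1*02:01,II,DQB1,0.555
DQB1*02:02,II,DQB1,-0.305
DQB1*03:01,II,DQB1,-0.625
DQB1*03:02,II,DQB1,0.717
DQB1*03:03,II,DQB1,0.585
DQB1*04:02,II,DQB1,0.437
DQB1*05:01,II,DQB1,0.052
DQB1*05:02,II,DQB1,-0.648
DQB1*05:03,II,DQB1,-0.413
DQB1*06:01,II,DQB1,-0.325
DQB1*06:02,II,DQB1,0.584
DQB1*06:03,II,DQB1,0.254
DQB1*06:04,II,DQB1,0.543
DQB1*06:09,II,DQB1,-0.226
DRB1*01:01,II,DRB1,0.576
DRB1*01:02,II,DRB1,-0.876
DRB1*01:03,II,DRB1,-0.354
DRB1*03:01,II,DRB1,-0.026
DRB1*04:01,II,DRB1,1.093
DRB1*04:02,II,DRB1,-0.622
DRB1*04:03,II,DRB1,-0.694
DRB1*04:04,II,DRB1,0.603
DRB1*04:05,II,DRB1,-0.261
DRB1*04:07,II,DRB1,-0.228
DRB1*04:08,II,DRB1,0.56
DRB1*07:01,II,DRB1,-0.452
DRB1*08:01,II,DRB1,0.424
DRB1*08:03,II,DRB1,-0.206
DRB1*09:01,II,DRB1,0.423
DRB1*10:01,II,DRB1,0.068
DRB1*11:01,II,DRB1,-0.369
DRB1*11:02,II,DRB1,-0.53
DRB1*11:03,II,DRB1,-0.705
DRB1*11:04,II,DRB1,-0.444
DRB1*12:01,II,DRB1,0.372
DRB1*13:01,II,DRB1,0.34
DRB1*13:02,II,DRB1,0.536
DRB1*13:03,II,DRB1,-0.61
DRB1*13:05,II,DRB1,-0.659
DRB1*14:01,II,DRB1,-0.265
DRB1*15:01,II,DRB1,0.965
DRB1*15:02,II,DRB1,-0.608
DRB1*16:01,II,DRB1,-0.437
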