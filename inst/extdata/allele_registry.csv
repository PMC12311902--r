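allele,class,gene,supertype
A*01:01,I,A,A01
A*02:01,I,A,A02
A*02:05,I,A,A02
A*03:01,I,A,A03
A*11:01,I,A,A03
A*23:01,I,A,A24
A*24:02,I,A,A24
A*25:01,I,A,A01
A*26:01,I,A,A01
A*29:01,I,A,A24
A*29:02,I,A,A01 A24
A*30:01,I,A,A01 A03
A*30:02,I,A,A01
A*31:01,I,A,A03
A*32:01,I,A,A01
A*33:01,I,A,A03
A*33:03,I,A,A03
A*36:01,I,A,A01
A*68:01,I,A,A03
A*68:02,I,A,A02
B*07:02,I,B,B07
B*08:01,I,B,B08
B*13:02,I,B,Unassigned
B*14:01,I,B,B27
B*14:02,I,B,B27
B*15:01,I,B,B62
B*15:17,I,B,B58
B*15:18,I,B,B27
B*18:01,I,B,B44
B*27:02,I,B,B27
B*27:05,I,B,B27
B*35:01,I,B,B07
B*35:02,I,B,B07
B*35:03,I,B,B07
B*35:08,I,B,B07
B*37:01,I,B,B44
B*38:01,I,B,B27
B*39:01,I,B,B27
B*39:06,I,B,B27
B*40:01,I,B,B44
B*40:02,I,B,B44
B*41:01,I,B,B44
B*41:02,I,B,B44
B*44:02,I,B,B44
B*44:03,I,B,B44
B*44:05,I,B,B44
B*45:01,I,B,B44
B*47:01,I,B,Unassigned
B*49:01,I,B,Unassigned
B*50:01,I,B,B44
B*51:01,I,B,B07
B*52:01,I,B,B62
B*55:01,I,B,B07
B*56:01,I,B,B07
B*57:01,I,B,B58
B*58:01,I,B,B58
C*01:02,I,C,
C*03:03,I,C,
C*04:01,I,C,
C*05:01,I,C,
C*06:02,I,C,
C*07:01,I,C,
C*07:02,I,C,
C*07:04,I,C,
C*12:02,I,C,
C*12:03,I,C,
C*14:02,I,C,
C*15:02,I,C,
C*16:01,I,C,
DPB1*01:01,II,DPB1,
DPB1*02:01,II,DPB1,
DPB1*02:02,II,DPB1,
DPB1*03:01,II,DPB1,
DPB1*04:01,II,DPB1,
DPB1*04:02,II,DPB1,
DPB1*05:01,II,DPB1,
DPB1*06:01,II,DPB1,
DPB1*09:01,II,DPB1,
DPB1*10:01,II,DPB1,
DPB1*11:01,II,DPB1,
DPB1*13:01,II,DPB1,
DPB1*14:01,II,DPB1,
DPB1*17:01,II,DPB1,
DPB1*19:01,II,DPB1,
DQB1*02:01,II,DQB1,
DQB1*02:02,II,DQB1,
DQB1*03:01,II,DQB1,
DQB1*03:02,II,DQB1,
DQB1*03:03,II,DQB1,
DQB1*04:02,II,DQB1,
DQB1*05:01,II,DQB1,
DQB1*05:02,II,DQB1,
DQB1*05:03,II,DQB1,
DQB1*06:01,II,DQB1,
DQB1*06:02,II,DQB1,
DQB1*06:03,II,DQB1,
DQB1*06:04,II,DQB1,
DQB1*06:09,II,DQB1,
DRB1*01:01,II,DRB1,
DRB1*01:02,II,DRB1,
DRB1*01:03,II,DRB1,
DRB1*03:01,II,DRB1,
DRB1*04:01,II,DRB1,
DRB1*04:02,II,DRB1,
DRB1*04:03,II,DRB1,
DRB1*04:04,II,DRB1,
DRB1*04:05,II,DRB1,
DRB1*04:07,II,DRB1,
DRB1*04:08,II,DRB1,
DRB1*07:01,II,DRB1,
DRB1*08:01,II,DRB1,
DRB1*08:03,II,DRB1,
DRB1*09:01,II,DRB1,
DRB1*10:01,II,DRB1,
DRB1*11:01,II,DRB1,
DRB1*11:02,II,DRB1,
DRB1*11:03,II,DRB1,
DRB1*11:04,II,DRB1,
DRB1*12:01,II,DRB1,
DRB1*13:01,II,DRB1,
DRB1*13:02,II,DRB1,
DRB1*13:03,II,DRB1,
DRB1*13:05,II,DRB1,
DRB1*14:01,II,DRB1,
DRB1*15:01,II,DRB1,
DRB1*15:02,II,DRB1,
DRB1*16:01,II,DRB1,
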