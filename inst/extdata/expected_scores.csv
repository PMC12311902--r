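allele,r_prime_expected
A*01:01,-0.0981
A*02:01,-0.06601
A*02:05,-0.11706
A*03:01,-0.02287
A*11:01,-0.13304
A*23:01,-0.14128
A*24:02,-0.06191
A*25:01,-0.06935
A*26:01,-0.13616
A*29:01,-0.08055
A*29:02,-0.10928
A*30:01,-0.08787
A*30:02,-0.11728
A*31:01,0.00081
A*32:01,-0.12997
A*33:01,-0.11542
A*33:03,-0.12972
A*36:01,-0.11615
A*68:01,-0.06584
A*68:02,-0.08632
B*07:02,0.00323
B*08:01,-0.05063
B*13:02,-0.07745
B*14:01,-0.11786
B*14:02,-0.11589
B*15:01,0.00777
B*15:17,-0.10458
B*15:18,-0.124
B*18:01,-0.15214
B*27:02,-0.09829
B*27:05,-0.04446
B*35:01,-0.09081
B*35:02,-0.13615
B*35:03,-0.14199
B*35:08,-0.15024
B*37:01,0.01478
B*38:01,-0.17444
B*39:01,-0.09179
B*39:06,-0.10054
B*40:01,-0.00427
B*40:02,-0.06165
B*41:01,-0.11417
B*41:02,-0.1469
B*44:02,-0.07697
B*44:03,-0.11213
B*44:05,-0.12451
B*45:01,-0.10965
B*47:01,-0.10636
B*49:01,-0.1575
B*50:01,-0.13779
B*51:01,-0.14575
B*52:01,-0.12171
B*55:01,-0.03946
B*56:01,-0.06161
B*57:01,-0.09192
B*58:01,-0.12279
C*01:02,-0.08364
C*03:03,-0.04563
C*04:01,-0.1521
C*05:01,-0.07476
C*06:02,-0.08138
C*07:01,-0.07739
C*07:02,0.01269
C*07:04,-0.12142
C*12:02,-0.12683
C*12:03,-0.15016
C*14:02,-0.14688
C*15:02,-0.13256
C*16:01,-0.09218
DPB1*01:01,-0.00218
DPB1*02:01,-0.14851
DPB1*02:02,-0.11065
DPB1*03:01,-0.07555
DPB1*04:01,-0.03509
DPB1*04:02,-0.08794
DPB1*05:01,-0.06835
DPB1*06:01,-0.09915
DPB1*09:01,-0.10201
DPB1*10:01,-0.15335
DPB1*11:01,-0.08137
DPB1*13:01,-0.14686
DPB1*14:01,-0.14786
DPB1*17:01,-0.1146
DPB1*19:01,-0.06244
DQB1*02:01,-0.05403
DQB1*02:02,-0.12581
DQB1*03:01,-0.1613
DQB1*03:02,-0.04474
DQB1*03:03,-0.0482
DQB1*04:02,-0.06698
DQB1*05:01,-0.09846
DQB1*05:02,-0.15057
DQB1*05:03,-0.13746
DQB1*06:01,-0.13615
DQB1*06:02,-0.05035
DQB1*06:03,-0.08316
DQB1*06:04,-0.0567
DQB1*06:09,-0.12162
DRB1*01:01,-0.04449
DRB1*01:02,-0.17229
DRB1*01:03,-0.12101
DRB1*03:01,-0.09058
DRB1*04:01,0.00772
DRB1*04:02,-0.14398
DRB1*04:03,-0.1578
DRB1*04:04,-0.04321
DRB1*04:05,-0.10505
DRB1*04:07,-0.10413
DRB1*04:08,-0.03819
DRB1*07:01,-0.13275
DRB1*08:01,-0.06066
DRB1*08:03,-0.11381
DRB1*09:01,-0.05353
DRB1*10:01,-0.0905
DRB1*11:01,-0.12326
DRB1*11:02,-0.13365
DRB1*11:03,-0.14712
DRB1*11:04,-0.1319
DRB1*12:01,-0.05823
DRB1*13:01,-0.06099
DRB1*13:02,-0.04509
DRB1*13:03,-0.14444
DRB1*13:05,-0.14817
DRB1*14:01,-0.11612
DRB1*15:01,0.00101
DRB1*15:02,-0.13911
DRB1*16:01,-0.12667
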