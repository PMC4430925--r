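# Default gene models: canonical-transcript protein lengths with
# cds_length_bp = 3 * (protein_length_aa + 1) (stop codon included).
# Domain intervals are 1-based, closed, non-overlapping, APPROXIMATE
# canonical annotations: NOTCH1 EGF repeats are laid out as 36
# equal-width repeats across the EGF region; NOTCH2-4 carry a single
# EGF span. Supply your own config for publication-grade boundaries.
genes:
  NOTCH1:
    protein_length_aa: 2555
    cds_length_bp: 7668
    domains:
    - name: EGF_1
      start: 20
      end: 58
    - name: EGF_2
      start: 59
      end: 97
    - name: EGF_3
      start: 98
      end: 136
    - name: EGF_4
      start: 137
      end: 175
    - name: EGF_5
      start: 176
      end: 214
    - name: EGF_6
      start: 215
      end: 253
    - name: EGF_7
      start: 254
      end: 292
    - name: EGF_8
      start: 293
      end: 331
    - name: EGF_9
      start: 332
      end: 370
    - name: EGF_10
      start: 371
      end: 409
    - name: EGF_11
      start: 410
      end: 448
    - name: EGF_12
      start: 449
      end: 488
    - name: EGF_13
      start: 489
      end: 527
    - name: EGF_14
      start: 528
      end: 566
    - name: EGF_15
      start: 567
      end: 605
    - name: EGF_16
      start: 606
      end: 644
    - name: EGF_17
      start: 645
      end: 683
    - name: EGF_18
      start: 684
      end: 722
    - name: EGF_19
      start: 723
      end: 761
    - name: EGF_20
      start: 762
      end: 800
    - name: EGF_21
      start: 801
      end: 839
    - name: EGF_22
      start: 840
      end: 878
    - name: EGF_23
      start: 879
      end: 917
    - name: EGF_24
      start: 918
      end: 957
    - name: EGF_25
      start: 958
      end: 996
    - name: EGF_26
      start: 997
      end: 1035
    - name: EGF_27
      start: 1036
      end: 1074
    - name: EGF_28
      start: 1075
      end: 1113
    - name: EGF_29
      start: 1114
      end: 1152
    - name: EGF_30
      start: 1153
      end: 1191
    - name: EGF_31
      start: 1192
      end: 1230
    - name: EGF_32
      start: 1231
      end: 1269
    - name: EGF_33
      start: 1270
      end: 1308
    - name: EGF_34
      start: 1309
      end: 1347
    - name: EGF_35
      start: 1348
      end: 1386
    - name: EGF_36
      start: 1387
      end: 1426
    - name: LNR
      start: 1449
      end: 1571
    - name: HD
      start: 1572
      end: 1735
    - name: TM
      start: 1739
      end: 1759
    - name: RAM
      start: 1760
      end: 1880
    - name: ANK
      start: 1927
      end: 2093
    - name: PEST
      start: 2480
      end: 2555
  NOTCH2:
    protein_length_aa: 2471
    cds_length_bp: 7416
    domains:
    - name: EGF
      start: 26
      end: 1420
    - name: LNR
      start: 1425
      end: 1543
    - name: HD
      start: 1545
      end: 1675
    - name: TM
      start: 1677
      end: 1697
    - name: RAM
      start: 1700
      end: 1820
    - name: ANK
      start: 1860
      end: 2010
    - name: PEST
      start: 2400
      end: 2471
  NOTCH3:
    protein_length_aa: 2321
    cds_length_bp: 6966
    domains:
    - name: EGF
      start: 40
      end: 1380
    - name: LNR
      start: 1384
      end: 1503
    - name: HD
      start: 1505
      end: 1640
    - name: TM
      start: 1643
      end: 1663
    - name: RAM
      start: 1666
      end: 1780
    - name: ANK
      start: 1820
      end: 1970
    - name: PEST
      start: 2250
      end: 2321
  NOTCH4:
    protein_length_aa: 2003
    cds_length_bp: 6012
    domains:
    - name: EGF
      start: 28
      end: 1170
    - name: LNR
      start: 1174
      end: 1290
    - name: HD
      start: 1295
      end: 1425
    - name: TM
      start: 1430
      end: 1450
    - name: RAM
      start: 1455
      end: 1570
    - name: ANK
      start: 1600
      end: 1750
    - name: PEST
      start: 1940
      end: 2003
  JAG1:
    protein_length_aa: 1218
    cds_length_bp: 3657
  JAG2:
    protein_length_aa: 1238
    cds_length_bp: 3717
  DLL1:
    protein_length_aa: 723
    cds_length_bp: 2172
  DLL4:
    protein_length_aa: 685
    cds_length_bp: 2058
  TP53:
    protein_length_aa: 393
    cds_length_bp: 1182
  HRAS:
    protein_length_aa: 189
    cds_length_bp: 570
  KRAS:
    protein_length_aa: 189
    cds_length_bp: 570
  NRAS:
    protein_length_aa: 189
    cds_length_bp: 570
  EGFR:
    protein_length_aa: 1210
    cds_length_bp: 3633
  ERBB2:
    protein_length_aa: 1255
    cds_length_bp: 3768
  ERBB3:
    protein_length_aa: 1342
    cds_length_bp: 4029
  ERBB4:
    protein_length_aa: 1308
    cds_length_bp: 3927
  APC:
    protein_length_aa: 2843
    cds_length_bp: 8532
  PTCH1:
    protein_length_aa: 1447
    cds_length_bp: 4344
  PTCH2:
    protein_length_aa: 1203
    cds_length_bp: 3612
  PABPN1:
    protein_length_aa: 306
    cds_length_bp: 921
  FPGT:
    protein_length_aa: 594
    cds_length_bp: 1785
  NONO:
    protein_length_aa: 471
    cds_length_bp: 1416

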