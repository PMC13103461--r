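case_id,object,label,source,value
1,mandible,Attempts,registration,3
2,mandible,Attempts,registration,1
3,mandible,Attempts,registration,1
4,mandible,Attempts,registration,2
5,mandible,Attempts,registration,1
6,mandible,Attempts,registration,1
7,mandible,Attempts,registration,2
8,mandible,Attempts,registration,2
9,mandible,Attempts,registration,1
10,mandible,Attempts,registration,1
11,mandible,Attempts,registration,1
1,mandible,FRE,registration,1.17
2,mandible,FRE,registration,1.42
3,mandible,FRE,registration,1.44
4,mandible,FRE,registration,1.35
5,mandible,FRE,registration,1.14
6,mandible,FRE,registration,0.9
7,mandible,FRE,registration,0.86
8,mandible,FRE,registration,1.14
9,mandible,FRE,registration,1.48
10,mandible,FRE,registration,1.08
11,mandible,FRE,registration,0.72
1,mandible,TRE_CONDYLE,registration,0.94
2,mandible,TRE_CONDYLE,registration,1.14
3,mandible,TRE_CONDYLE,registration,1.13
4,mandible,TRE_CONDYLE,registration,1.1
5,mandible,TRE_CONDYLE,registration,0.84
6,mandible,TRE_CONDYLE,registration,0.74
7,mandible,TRE_CONDYLE,registration,0.62
8,mandible,TRE_CONDYLE,registration,0.84
9,mandible,TRE_CONDYLE,registration,1.12
10,mandible,TRE_CONDYLE,registration,0.88
11,mandible,TRE_CONDYLE,registration,0.59
1,mandible,TRE_CENTER,registration,0.88
2,mandible,TRE_CENTER,registration,1.06
3,mandible,TRE_CENTER,registration,1.09
4,mandible,TRE_CENTER,registration,0.95
5,mandible,TRE_CENTER,registration,0.67
6,mandible,TRE_CENTER,registration,0.68
7,mandible,TRE_CENTER,registration,0.49
8,mandible,TRE_CENTER,registration,0.73
9,mandible,TRE_CENTER,registration,0.93
10,mandible,TRE_CENTER,registration,0.86
11,mandible,TRE_CENTER,registration,0.56
1,graft,Attempts,registration,9
2,graft,Attempts,registration,2
3,graft,Attempts,registration,1
4,graft,Attempts,registration,1
5,graft,Attempts,registration,4
6,graft,Attempts,registration,1
7,graft,Attempts,registration,1
8,graft,Attempts,registration,1
9,graft,Attempts,registration,8
10,graft,Attempts,registration,1
11,graft,Attempts,registration,1
1,graft,FRE,registration,1.51
2,graft,FRE,registration,1.91
3,graft,FRE,registration,1.32
4,graft,FRE,registration,2.01
5,graft,FRE,registration,2.44
6,graft,FRE,registration,1.51
7,graft,FRE,registration,4
8,graft,FRE,registration,1.94
9,graft,FRE,registration,1.35
10,graft,FRE,registration,1.64
11,graft,FRE,registration,1.73
1,graft,TRE_CONDYLE,registration,1.25
2,graft,TRE_CONDYLE,registration,1.19
3,graft,TRE_CONDYLE,registration,0.74
4,graft,TRE_CONDYLE,registration,0.99
5,graft,TRE_CONDYLE,registration,1.26
6,graft,TRE_CONDYLE,registration,0.79
7,graft,TRE_CONDYLE,registration,2.12
8,graft,TRE_CONDYLE,registration,1.03
9,graft,TRE_CONDYLE,registration,0.8
10,graft,TRE_CONDYLE,registration,0.97
11,graft,TRE_CONDYLE,registration,0.97
1,graft,TRE_CENTER,registration,0.88
2,graft,TRE_CENTER,registration,0.9
3,graft,TRE_CENTER,registration,0.57
4,graft,TRE_CENTER,registration,0.63
5,graft,TRE_CENTER,registration,0.86
6,graft,TRE_CENTER,registration,0.52
7,graft,TRE_CENTER,registration,1.44
8,graft,TRE_CENTER,registration,0.76
9,graft,TRE_CENTER,registration,0.55
10,graft,TRE_CENTER,registration,0.69
11,graft,TRE_CENTER,registration,0.68
1,graft,Tx_total,cbct,1.39
2,graft,Tx_total,cbct,1.82
3,graft,Tx_total,cbct,3.42
4,graft,Tx_total,cbct,4.13
5,graft,Tx_total,cbct,1.96
6,graft,Tx_total,cbct,1.5
7,graft,Tx_total,cbct,3.87
8,graft,Tx_total,cbct,1.35
9,graft,Tx_total,cbct,1.54
10,graft,Tx_total,cbct,1.8
11,graft,Tx_total,cbct,1.02
1,graft,Segment_1,cbct,1.79
2,graft,Segment_1,cbct,1.56
3,graft,Segment_1,cbct,3.86
4,graft,Segment_1,cbct,6.08
5,graft,Segment_1,cbct,1.86
6,graft,Segment_1,cbct,2.18
7,graft,Segment_1,cbct,3.82
8,graft,Segment_1,cbct,1.49
9,graft,Segment_1,cbct,1.94
10,graft,Segment_1,cbct,1.93
11,graft,Segment_1,cbct,1.06
1,graft,Segment_2,cbct,0.81
2,graft,Segment_2,cbct,2.02
3,graft,Segment_2,cbct,3.06
4,graft,Segment_2,cbct,3.86
5,graft,Segment_2,cbct,1.96
6,graft,Segment_2,cbct,1.15
7,graft,Segment_2,cbct,3.98
8,graft,Segment_2,cbct,1.23
9,graft,Segment_2,cbct,1.13
10,graft,Segment_2,cbct,1.65
11,graft,Segment_2,cbct,0.98
4,graft,Segment_3,cbct,1.43
5,graft,Segment_3,cbct,2.04
6,graft,Segment_3,cbct,0.61
7,graft,Segment_3,cbct,3.72
4,graft,Segment_4,cbct,1.11
1,graft,CON,cbct,1.04
2,graft,CON,cbct,2.33
3,graft,CON,cbct,4.01
4,graft,CON,cbct,6.68
5,graft,CON,cbct,2.02
6,graft,CON,cbct,3.62
7,graft,CON,cbct,4.04
8,graft,CON,cbct,2.38
9,graft,CON,cbct,2.71
10,graft,CON,cbct,2.41
11,graft,CON,cbct,1.21
1,graft,ANG,cbct,0.93
2,graft,ANG,cbct,2.16
3,graft,ANG,cbct,4.56
4,graft,ANG,cbct,5.43
5,graft,ANG,cbct,1.82
6,graft,ANG,cbct,1.62
7,graft,ANG,cbct,2.91
8,graft,ANG,cbct,1.51
9,graft,ANG,cbct,1.74
10,graft,ANG,cbct,1.69
11,graft,ANG,cbct,1.69
1,graft,JUN,cbct,1.12
2,graft,JUN,cbct,1.91
3,graft,JUN,cbct,0.32
4,graft,JUN,cbct,0.82
5,graft,JUN,cbct,2.45
6,graft,JUN,cbct,0.31
7,graft,JUN,cbct,2.21
8,graft,JUN,cbct,0.76
9,graft,JUN,cbct,1.24
10,graft,JUN,cbct,0.81
11,graft,JUN,cbct,0.5
1,graft,CON,navigation,1.09
2,graft,CON,navigation,1.42
3,graft,CON,navigation,1.51
4,graft,CON,navigation,9.16
5,graft,CON,navigation,1.38
6,graft,CON,navigation,2.48
7,graft,CON,navigation,2.79
8,graft,CON,navigation,0.93
9,graft,CON,navigation,2.27
10,graft,CON,navigation,1.23
11,graft,CON,navigation,2.23
1,graft,ANG,navigation,1.42
2,graft,ANG,navigation,0.71
3,graft,ANG,navigation,1.73
4,graft,ANG,navigation,5.64
5,graft,ANG,navigation,1.19
6,graft,ANG,navigation,1.05
7,graft,ANG,navigation,2.23
8,graft,ANG,navigation,1.72
9,graft,ANG,navigation,2.17
10,graft,ANG,navigation,1.43
11,graft,ANG,navigation,1.8
1,graft,JUN,navigation,1.89
2,graft,JUN,navigation,3.11
3,graft,JUN,navigation,2.29
4,graft,JUN,navigation,2.02
5,graft,JUN,navigation,1.12
6,graft,JUN,navigation,1.42
7,graft,JUN,navigation,5.78
8,graft,JUN,navigation,1.08
9,graft,JUN,navigation,1.27
10,graft,JUN,navigation,0.72
11,graft,JUN,navigation,2.22
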