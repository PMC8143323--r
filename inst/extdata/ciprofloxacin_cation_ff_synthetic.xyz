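43
ciprofloxacin N-protonated cation, force-field 3D build (synthetic starting geometry)
C         -0.68192        0.96265        0.41801
C          0.59872        0.35193       -0.05661
C         -0.66762       -0.46277       -0.08828
N         -1.46827       -0.79321       -1.28919
C         -0.83446       -1.01630       -2.50148
C         -1.43522       -1.35927       -3.65853
C         -2.89920       -1.53417       -3.62371
O         -3.52012       -1.78961       -4.65273
C         -3.58911       -1.43413       -2.32285
C         -4.94416       -1.75099       -2.25337
C         -5.57373       -1.74397       -1.01836
C         -4.89984       -1.40580        0.17102
C         -3.55206       -1.01920        0.05064
C         -2.86434       -1.06302       -1.17789
N         -5.50744       -1.48881        1.41466
C         -6.47294       -2.56229        1.70569
C         -7.82403       -1.95927        2.12282
N         -7.61676       -0.97363        3.25486
C         -6.63368        0.11931        2.89866
C         -5.28141       -0.48409        2.45989
F         -6.88141       -2.05045       -0.98134
C         -0.62934       -1.55278       -4.88099
O          0.58717       -1.42918       -4.90473
O         -1.34262       -1.89084       -5.97821
H         -1.12142        1.72853       -0.21241
H         -0.80576        1.13326        1.47968
H          1.34021        0.10727        0.69907
H          1.02880        0.72233       -0.97774
H         -0.69336       -1.26756        0.64538
H          0.24620       -0.89257       -2.46708
H         -5.50633       -2.02822       -3.14072
H         -3.00441       -0.74569        0.94761
H         -6.07430       -3.16578        2.53084
H         -6.61470       -3.26177        0.87537
H         -8.50886       -2.72682        2.49353
H         -8.29521       -1.40458        1.30509
H         -7.27676       -1.47970        4.08236
H         -8.51945       -0.55506        3.50992
H         -6.52273        0.74994        3.78494
H         -7.09181        0.69795        2.08956
H         -4.79178       -0.96321        3.31601
H         -4.63547        0.33551        2.12632
H         -2.31942       -1.94589       -5.83677
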