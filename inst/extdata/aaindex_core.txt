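H FUKS010101
D Surface composition of amino acids in intracellular proteins of thermophiles (percent) (Fukuchi-Nishikawa, 2001)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     4.47    8.48    3.89    7.05    0.29    2.87   16.56    8.29    1.74     3.3
     5.06   12.98    1.71    2.32    5.41    4.27    3.83    0.67    2.75    4.05
//
H JOND920102
D Relative mutability (Jones et al., 1992)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      100      83     104      86      44      84      77      50      91     103
       54      72      93      51      58     117     107      25      50      98
//
H PONP800107
D Accessibility reduction ratio (Ponnuswamy et al., 1980)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      3.7    2.53    2.12     2.6    3.03     2.7     3.3    3.13    3.57    7.69
     5.88    1.79    5.21     6.6    2.12    2.43     2.6    6.25    3.03    7.14
//
H QIAN880134
D Weights for coil at the window position of 1 (Qian-Sejnowski, 1988)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    -0.24   -0.04    0.45    0.65   -0.38    0.01    0.07    0.85   -0.21   -0.65
     -0.8    0.17   -0.71   -0.61    2.27    0.33    0.13   -0.44   -0.49   -0.99
//
H GEOR030102
D Linker propensity from 1-linker dataset (George-Heringa, 2003)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.974   1.129   0.988   0.892   0.972   1.092   1.054   0.845   0.949   0.928
     1.11   0.946   0.923   1.122   1.362   0.932   1.023   0.879   0.902   0.923
//
H OOBM850102
D Optimized propensity to form reverse turn (Oobatake et al., 1985)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.34    0.95    2.49    3.32    1.07    1.49     2.2    2.07    1.27    0.66
     0.54    0.61     0.7     0.8    2.12    0.94    1.09   -4.65   -0.17    1.32
//
H ARGP820102
D Signal sequence helical potential (Argos et al., 1982)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.18     0.2    0.23    0.05    1.89    0.72    0.11    0.49    0.31    1.45
     3.23    0.06    2.67    1.96    0.76    0.97    0.84    0.77    0.39    1.08
//
H PRAM820103
D Correlation coefficient in regression analysis (Prabhakaran-Ponnuswamy, 1982)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.687    0.59   0.489   0.632   0.263   0.527   0.669    0.67   0.594   0.564
    0.541   0.407   0.328   0.577     0.6   0.692   0.713   0.632   0.495   0.529
//
H PRAM820101
D Intercept in regression analysis (Prabhakaran-Ponnuswamy, 1982)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.305   0.227   0.322   0.335   0.339   0.306   0.282   0.352   0.215   0.278
    0.262   0.391    0.28   0.195   0.346   0.326   0.251   0.291   0.293   0.291
//
H ZIMJ680104
D Isoelectric point (Zimmerman et al., 1968)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
        6   10.76    5.41    2.77    5.05    5.65    3.22    5.97    7.59    6.02
     5.98    9.74    5.74    5.48     6.3    5.68    5.66    5.89    5.66    5.96
//
H CHOP780209
D Normalized frequency of C-terminal beta-sheet (Chou-Fasman, 1978b)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0.75     0.9    1.21    0.85    1.11    0.65    0.55    0.74     0.9    1.35
     1.27    0.74    0.95     1.5     0.4    0.79    0.75    1.19    1.96    1.79
//
H CHOP780213
D Frequency of the 2nd residue in turn (Chou-Fasman, 1978b)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.076   0.106   0.083    0.11   0.053   0.098    0.06   0.085   0.047   0.034
    0.025   0.115   0.082   0.041   0.301   0.139   0.108   0.013   0.065   0.048
//
H VASM830101
D Relative population of conformational state A (Vasquez et al., 1983)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.135   0.296   0.196   0.289   0.159   0.236   0.184   0.051   0.223   0.173
    0.215    0.17   0.239   0.087   0.151    0.01     0.1   0.166   0.066   0.285
//
H VASM830102
D Relative population of conformational state C (Vasquez et al., 1983)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.507   0.459   0.287   0.223   0.592   0.383   0.445    0.39    0.31   0.111
    0.619   0.559   0.431   0.077   0.739   0.689   0.785    0.16    0.06   0.356
//
H DAYM780201
D Relative mutability (Dayhoff et al., 1978b)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      100      65     134     106      20      93     102      49      66      96
       40      56      94      41      56     120      97      18      41      74
//
H BROC820102
D Retention coefficient in HFBA (Browne et al., 1982)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      3.9     3.2    -2.8    -2.8   -14.3     1.8    -7.5    -2.3       2      11
       15    -2.5     4.1    14.7     5.6    -3.5     1.1    17.8     3.8     2.1
//
H SUYM030101
D Linker propensity index (Suyama-Ohara, 2003)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   -0.058       0   0.027   0.016   0.447  -0.073  -0.128   0.331   0.195    0.06
    0.138  -0.112   0.275    0.24  -0.478  -0.177  -0.163   0.564   0.322  -0.052
//
H FASG760103
D Optical rotation (Fasman, 1976)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      1.8    12.5    -5.6    5.05   -16.5     6.3      12       0   -38.5    12.4
      -11    14.6     -10   -34.5   -86.2    -7.5     -28   -33.7     -10    5.63
//
H LIFS790102
D Conformational preference for parallel beta-strands (Lifson-Sander, 1979)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
        1    0.68    0.54     0.5    0.91    0.28    0.59    0.79    0.38     2.6
     1.42    0.59    1.49     1.3    0.35     0.7    0.59    0.89    1.08    2.63
//
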