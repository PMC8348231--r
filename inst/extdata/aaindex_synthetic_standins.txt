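H KOSJ950115
D SYNTHETIC STAND-IN (not the published scale): placeholder values for KOSJ950115
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.91    1.05   -0.15    0.38   -0.63   -0.13    -0.8   -1.28   -0.11   -0.27
    -1.26   -0.16   -0.04    0.15    1.58    1.58   -0.42    0.79   -0.89    0.22
//
H DOSZ010102
D SYNTHETIC STAND-IN (not the published scale): placeholder values for DOSZ010102
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.54    0.56       1   -0.58    0.85    1.23   -0.43   -0.53    0.61   -0.99
    -0.15   -1.37   -0.45   -0.35    0.68   -0.58   -0.77    1.64   -1.25   -0.64
//
H MIRL960101
D SYNTHETIC STAND-IN (not the published scale): placeholder values for MIRL960101
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      0.2   -2.05   -0.18   -0.12    0.33   -1.38    2.22    1.34    -0.4   -0.24
     1.33   -0.11    1.43    0.17    0.23    1.22    0.54    0.13   -0.86      -1
//
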