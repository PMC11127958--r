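
     RDKit          3D

 12 12  0  0  0  0  0  0  0  0999 V2000
    1.8930    0.3657    1.9316 F   0  0  0  0  0  0  0  0  0  0  0  0
    0.9346    0.2098    1.0008 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2600    0.7945    1.0952 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2073    0.6082    0.1234 N   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0083   -0.1700   -0.9889 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8767   -0.3166   -1.8410 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.2199   -0.7681   -1.0811 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.2380   -0.6487   -0.1668 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.3166   -1.2129   -0.3104 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5238    1.4305    1.9325 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.1164    1.0529    0.1947 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.3905   -1.3454   -1.8898 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  2  0
  3  4  1  0
  4  5  1  0
  5  6  2  0
  5  7  1  0
  7  8  1  0
  8  9  2  0
  8  2  1  0
  3 10  1  0
  4 11  1  0
  7 12  1  0
M  END
$$$$
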