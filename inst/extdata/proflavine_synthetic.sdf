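
     RDKit          3D

 27 29  0  0  0  0  0  0  0  0999 V2000
    4.8334    1.1155   -0.0156 N   0  0  0  0  0  0  0  0  0  0  0  0
    3.6220    0.4254   -0.1454 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.6039   -0.9674   -0.1282 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.3910   -1.6557   -0.1381 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.1783   -0.9490   -0.1223 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0584   -1.6030   -0.1338 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2442   -0.8615   -0.1022 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5051   -1.4779   -0.1273 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.6648   -0.7039   -0.0920 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.5817    0.6828    0.0111 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.7394    1.4658   -0.0732 N   0  0  0  0  0  0  0  0  0  0  0  0
   -2.3178    1.2828   -0.0243 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1429    0.5403   -0.0568 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0428    1.1766   -0.0479 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.1792    0.4565   -0.0810 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.4050    1.1123   -0.0703 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.6354    0.6203   -0.3924 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.7926    2.0801   -0.3317 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.5339   -1.5292   -0.1075 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.3994   -2.7429   -0.1445 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0979   -2.6889   -0.1673 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5924   -2.5598   -0.1879 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.6331   -1.1943   -0.1452 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.6293    2.4035    0.3016 H   0  0  0  0  0  0  0  0  0  0  0  0
   -5.5761    1.0078    0.2741 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.2346    2.3666   -0.0207 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.4008    2.1975   -0.0069 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  2  0
  3  4  1  0
  4  5  2  0
  5  6  1  0
  6  7  2  0
  7  8  1  0
  8  9  2  0
  9 10  1  0
 10 11  1  0
 10 12  2  0
 12 13  1  0
 13 14  2  0
 14 15  1  0
 15 16  2  0
 16  2  1  0
 15  5  1  0
 13  7  1  0
  1 17  1  0
  1 18  1  0
  3 19  1  0
  4 20  1  0
  6 21  1  0
  8 22  1  0
  9 23  1  0
 11 24  1  0
 11 25  1  0
 12 26  1  0
 16 27  1  0
M  END
$$$$
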