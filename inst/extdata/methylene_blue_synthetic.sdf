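
     RDKit          3D

 39 40  0  0  0  0  0  0  0  0999 V2000
    6.2674   -0.3440    0.2815 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.1331    0.3906   -0.2776 N   0  0  0  0  0  0  0  0  0  0  0  0
    5.3322    1.8308   -0.4379 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.8395   -0.1004   -0.0779 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.6952    0.6702   -0.3311 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.3904    0.1673   -0.1442 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0178    1.2673   -0.4945 S   0  0  0  0  0  3  0  0  0  0  0  0
   -1.3850    0.2142   -0.1208 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.6751    0.7606   -0.2868 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.8406    0.0227   -0.0328 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.6323   -1.2855    0.4234 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.3450   -1.8274    0.5881 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1993   -1.1068    0.3222 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0244   -1.7374    0.5158 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.1676   -1.1478    0.2992 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.2924   -1.9113    0.5323 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.5944   -1.4127    0.3471 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.1196    0.5671   -0.1812 N   0  0  0  0  0  0  0  0  0  0  0  0
   -6.2768   -0.3271   -0.1927 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.2809    1.8162   -0.9251 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 Cl  0  0  0  0  0 15  0  0  0  0  0  0
    6.1874   -0.4210    1.3715 H   0  0  0  0  0  0  0  0  0  0  0  0
    7.2161    0.1553    0.0543 H   0  0  0  0  0  0  0  0  0  0  0  0
    6.3446   -1.3458   -0.1543 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.8166    2.2053   -1.3288 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.9851    2.3767    0.4463 H   0  0  0  0  0  0  0  0  0  0  0  0
    6.3914    2.0727   -0.5811 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.7908    1.6918   -0.6865 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.7418    1.7913   -0.6215 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.4669   -1.9341    0.6723 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.2506   -2.8522    0.9419 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.1693   -2.9389    0.8687 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.4102   -2.1007    0.5477 H   0  0  0  0  0  0  0  0  0  0  0  0
   -6.2080   -1.0489   -1.0141 H   0  0  0  0  0  0  0  0  0  0  0  0
   -6.3756   -0.8599    0.7591 H   0  0  0  0  0  0  0  0  0  0  0  0
   -7.2106    0.2317   -0.3213 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.7485    2.6396   -0.4370 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.9277    1.7081   -1.9566 H   0  0  0  0  0  0  0  0  0  0  0  0
   -6.3324    2.1221   -0.9661 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  2  4  1  0
  4  5  2  0
  5  6  1  0
  6  7  2  0
  7  8  1  0
  8  9  2  0
  9 10  1  0
 10 11  2  0
 11 12  1  0
 12 13  2  0
 13 14  1  0
 14 15  2  0
 15 16  1  0
 16 17  2  0
 10 18  1  0
 18 19  1  0
 18 20  1  0
 17  4  1  0
 15  6  1  0
 13  8  1  0
  1 22  1  0
  1 23  1  0
  1 24  1  0
  3 25  1  0
  3 26  1  0
  3 27  1  0
  5 28  1  0
  9 29  1  0
 11 30  1  0
 12 31  1  0
 16 32  1  0
 17 33  1  0
 19 34  1  0
 19 35  1  0
 19 36  1  0
 20 37  1  0
 20 38  1  0
 20 39  1  0
M  CHG  2   7   1  21  -1
M  END
$$$$
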