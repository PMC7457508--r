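@<TRIPOS>MOLECULE
*****
 9 8 0 0 0
SMALL
GASTEIGER

@<TRIPOS>ATOM
      1 C           0.9965    0.0656   -0.0763 C.3     1  UNL1       -0.0418
      2 C           2.5108    0.0726   -0.0743 C.3     1  UNL1        0.0414
      3 O           2.9925    0.9527    0.9304 O.3     1  UNL1       -0.3953
      4 H           0.6117   -0.6165   -0.8395 H       1  UNL1        0.0252
      5 H           0.6045    1.0693   -0.2709 H       1  UNL1        0.0252
      6 H           0.6111   -0.2431    0.9010 H       1  UNL1        0.0252
      7 H           2.9023    0.3975   -1.0432 H       1  UNL1        0.0554
      8 H           2.8978   -0.9288    0.1356 H       1  UNL1        0.0554
      9 H           2.6529    1.8414    0.7294 H       1  UNL1        0.2094
@<TRIPOS>BOND
     1     1     2    1
     2     1     4    1
     3     1     5    1
     4     1     6    1
     5     2     3    1
     6     2     7    1
     7     2     8    1
     8     3     9    1
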