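COMPND    UNNAMED
AUTHOR    GENERATED BY OPEN BABEL 3.1.0
HETATM    1  C   UNL     1       0.997   0.066  -0.076  1.00  0.00           C  
HETATM    2  C   UNL     1       2.511   0.073  -0.074  1.00  0.00           C  
HETATM    3  O   UNL     1       2.993   0.953   0.930  1.00  0.00           O  
HETATM    4  H   UNL     1       0.612  -0.617  -0.840  1.00  0.00           H  
HETATM    5  H   UNL     1       0.605   1.069  -0.271  1.00  0.00           H  
HETATM    6  H   UNL     1       0.611  -0.243   0.901  1.00  0.00           H  
HETATM    7  H   UNL     1       2.902   0.398  -1.043  1.00  0.00           H  
HETATM    8  H   UNL     1       2.898  -0.929   0.136  1.00  0.00           H  
HETATM    9  H   UNL     1       2.653   1.841   0.729  1.00  0.00           H  
CONECT    1    2    4    5    6                                       
CONECT    2    1    3    7    8                                       
CONECT    3    2    9                                                 
CONECT    4    1                                                      
CONECT    5    1                                                      
CONECT    6    1                                                      
CONECT    7    2                                                      
CONECT    8    2                                                      
CONECT    9    3                                                      
MASTER        0    0    0    0    0    0    0    0    9    0    9    0
END
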