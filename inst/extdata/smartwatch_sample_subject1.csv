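Acc_x,Acc_y,Acc_z,Gyr_x,Gyr_y,Gyr_z,Ori_x,Ori_y,Ori_z
0.006494,0.009239,0.01121,0.086356,0.029508,0.011415,0.45407,0.70815,0.070161
-0.00074,0.01422,0.001814,0.088319,0.029273,0.027723,0.455669,0.708618,0.070167
-0.00668,0.013277,-0.00159,0.066002,0.026148,0.058603,0.456869,0.709155,0.070393
-0.00844,0.017108,0.001519,0.037187,0.023975,0.072369,0.457283,0.70961,0.070874
-0.00716,0.013046,-0.00435,0.019389,0.026953,0.083881,0.457445,0.710026,0.071477
0.003638,0.006969,-0.00419,0.010959,0.020459,0.093629,0.457578,0.710534,0.072157
0.011639,0.002621,-0.00286,0.029967,0.015235,0.077567,0.457893,0.710999,0.072829
0.012988,0.001942,-0.01286,0.070353,0.018348,0.053111,0.45838,0.711309,0.073376
0.01261,0.007601,-0.01088,0.115285,0.029243,0.035008,0.459069,0.711681,0.073653
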