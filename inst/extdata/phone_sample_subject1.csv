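Acc_x,Acc_y,Acc_z,Gyr_x,Gyr_y,Gyr_z,Ori_x,Ori_y,Ori_z
-0.44313,-8.78151,4.868727,-10.784,0.039824,-5.61297,2.446671,-1.38939,-18.3264
-0.48447,-8.56189,3.485494,-12.9766,-0.40324,-2.60337,0.356771,1.152709,-2.50698
-0.61656,-8.61197,2.981159,-13.828,-0.51613,-1.65867,-0.28343,1.931627,2.336218
-0.77201,-8.78855,3.000329,-13.7056,-0.46182,-1.93873,-0.28343,1.931627,2.336218
-0.88342,-8.94843,3.187611,-12.9766,-0.40324,-2.60337,-0.28343,1.931627,2.336218
-0.88342,-8.94843,3.187611,-11.9682,-0.46815,-2.97202,-0.28343,1.931627,2.336218
-0.72352,-8.68269,2.726951,-10.8453,-0.6436,-3.00261,-0.28343,1.931627,2.336218
-0.43086,-8.19468,1.860314,-9.73243,-0.88144,-2.81264,-0.28343,1.931627,2.704359
-0.05149,-7.56522,0.724398,-8.75415,-1.13354,-2.51963,-0.28343,1.931627,2.985879
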