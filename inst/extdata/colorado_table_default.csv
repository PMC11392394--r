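kind,bound,points
sofa,5,1
sofa,9,2
sofa,12,3
sofa,24,4
age,18,0
age,50,1
age,60,2
age,70,3
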