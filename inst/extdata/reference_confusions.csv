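kernel,class,n,class_1,class_2,class_3,class_4
gaussian,1,11,10,1,0,0
gaussian,2,10,1,9,0,0
gaussian,3,8,0,0,7,1
gaussian,4,11,0,0,0,11
polynomial,1,10,9,1,0,0
polynomial,2,10,0,10,0,0
polynomial,3,10,0,0,10,0
polynomial,4,10,0,0,1,9
sigmoid,1,9,9,0,0,0
sigmoid,2,8,1,7,0,0
sigmoid,3,10,0,0,9,1
sigmoid,4,13,0,0,1,12
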