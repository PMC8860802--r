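case,region,centers,points
case1,bleb,1,11
case1,nonbleb,1,135
case2,bleb,1,8
case2,nonbleb,1,144
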