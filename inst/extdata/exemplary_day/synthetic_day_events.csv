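type,t,value,fat_g,protein_g
meal,428.09025800786912,32.0000000000000000,24,11
meal,1124.04099469073117,41.0000000000000000,16,31
bolus,438.15238999086432,3.0000000000000000,NA,NA
bolus,1131.23389358748682,4.2000000000000002,NA,NA
exercise,814.24142600968480,NA,NA,NA
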