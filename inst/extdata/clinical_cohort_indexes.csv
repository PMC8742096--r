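id,CP,CI,AI,AAI,PAI,OCLR,initial,final,flag_AI,flag_AAI,flag_PAI,flag_OCLR
H1,435,85,-2,-2,0,101,Healthy,Healthy,FALSE,FALSE,FALSE,FALSE
H2,487,84,1,2,-1,99,Healthy,Healthy,FALSE,FALSE,FALSE,FALSE
H3,480,81,2,0,2,99,Healthy,Healthy,FALSE,FALSE,FALSE,FALSE
H4,423,81,-2,2,-4,101,Healthy,Healthy,FALSE,FALSE,FALSE,FALSE
H5,453,78,-3,1,-3,102,Healthy,Healthy,FALSE,FALSE,FALSE,FALSE
H6,493,78,4,1,1,98,Healthy,Healthy,FALSE,FALSE,FALSE,FALSE
H7,424,81,-2,0,-2,101,Healthy,Healthy,FALSE,FALSE,FALSE,FALSE
H8,404,85,3,2,2,98,Healthy,Healthy,FALSE,FALSE,FALSE,FALSE
P1,401,84,-4,-5,1,103,DP,DP,FALSE,TRUE,FALSE,FALSE
P2,410,84,-12,-2,-10,108,DP,DP,TRUE,FALSE,TRUE,TRUE
P3,376,89,-9,-3,-6,106,DP,DP,TRUE,FALSE,TRUE,FALSE
P4,415,90,-10,-3,-8,105,DP,DP,TRUE,FALSE,TRUE,FALSE
P5,405,89,5,9,-4,97,DP,DP,TRUE,TRUE,FALSE,FALSE
P6,478,87,-13,-4,-9,108,DP,DP,TRUE,FALSE,TRUE,TRUE
P7,503,76,9,1,8,94,DP,DP,TRUE,FALSE,TRUE,FALSE
P8,439,87,-8,-4,-4,104,DP,DP,TRUE,FALSE,FALSE,FALSE
P9,372,79,4,9,-4,98,DP,DP,FALSE,TRUE,FALSE,FALSE
P10,460,86,12,5,7,93,Healthy,DP,TRUE,TRUE,TRUE,TRUE
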