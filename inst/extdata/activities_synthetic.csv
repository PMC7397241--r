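smiles,target_id,target_is_kinase,activity_type,pchembl
Cc1ccc2ncnc(N)c2c1,KIN1,TRUE,IC50,6.5
COc1ccccc1,KIN1,TRUE,IC50,6.0
CCc1ccccc1,KIN1,TRUE,Ki,6.01
Clc1ccccc1,GPCR1,FALSE,IC50,8.0
Brc1ccccc1,KIN2,TRUE,other,7.5
Ic1ccccc1,KIN2,TRUE,Kd,7.2
Cc1ccccc1,KIN1,TRUE,IC50,5.2
CCO,KIN1,TRUE,IC50,9.0
c1ccncc1,KIN3,TRUE,Ki,6.8
Cc1ccc2ncnc(N)c2c1,KIN9,TRUE,Kd,7.9
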