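compound_id,name,smiles
FIX001,chlorobenzene,Clc1ccccc1
FIX002,"1,2-dichlorobenzene",Clc1ccccc1Cl
FIX003,"1,3-dichlorobenzene",Clc1cccc(Cl)c1
FIX004,"1,4-dichlorobenzene",Clc1ccc(Cl)cc1
FIX005,"1,2,3-trichlorobenzene",Clc1cccc(Cl)c1Cl
FIX006,"1,2,4-trichlorobenzene",Clc1ccc(Cl)c(Cl)c1
FIX007,"1,3,5-trichlorobenzene",Clc1cc(Cl)cc(Cl)c1
FIX008,"1,2,3,4-tetrachlorobenzene",Clc1ccc(Cl)c(Cl)c1Cl
FIX009,"1,2,4,5-tetrachlorobenzene",Clc1cc(Cl)c(Cl)cc1Cl
FIX010,pentachlorobenzene,Clc1cc(Cl)c(Cl)c(Cl)c1Cl
FIX011,hexachlorobenzene,Clc1c(Cl)c(Cl)c(Cl)c(Cl)c1Cl
FIX012,bromobenzene,Brc1ccccc1
FIX013,biphenyl,c1ccc(-c2ccccc2)cc1
FIX014,2-chlorobiphenyl,Clc1ccccc1-c1ccccc1
FIX015,3-chlorobiphenyl,Clc1cccc(-c2ccccc2)c1
FIX016,4-chlorobiphenyl,Clc1ccc(-c2ccccc2)cc1
FIX017,"2,2'-dichlorobiphenyl",Clc1ccccc1-c1ccccc1Cl
FIX018,"4,4'-dichlorobiphenyl",Clc1ccc(-c2ccc(Cl)cc2)cc1
FIX019,"2,4,4'-trichlorobiphenyl",Clc1ccc(-c2ccc(Cl)cc2Cl)cc1
FIX020,"2,2',5,5'-tetrachlorobiphenyl",Clc1ccc(Cl)c(-c2cc(Cl)ccc2Cl)c1
FIX021,"2,3',4,4'-tetrachlorobiphenyl",Clc1ccc(-c2ccc(Cl)c(Cl)c2)c(Cl)c1
FIX022,"2,2',4,5,5'-pentachlorobiphenyl",Clc1cc(-c2cc(Cl)ccc2Cl)c(Cl)cc1Cl
FIX023,"2,2',4,4',5,5'-hexachlorobiphenyl",Clc1cc(-c2cc(Cl)c(Cl)cc2Cl)c(Cl)cc1Cl
FIX024,"2,2',3,4,4',5,5'-heptachlorobiphenyl",Clc1cc(-c2cc(Cl)c(Cl)cc2Cl)c(Cl)c(Cl)c1Cl
FIX025,decachlorobiphenyl,Clc1c(Cl)c(Cl)c(-c2c(Cl)c(Cl)c(Cl)c(Cl)c2Cl)c(Cl)c1Cl
FIX026,4-bromobiphenyl,Brc1ccc(-c2ccccc2)cc1
FIX027,naphthalene,c1ccc2ccccc2c1
FIX028,1-methylnaphthalene,Cc1cccc2ccccc12
FIX029,2-methylnaphthalene,Cc1ccc2ccccc2c1
FIX030,acenaphthylene,C1=Cc2cccc3cccc1c23
FIX031,acenaphthene,C1Cc2cccc3cccc1c23
FIX032,fluorene,C1c2ccccc2-c2ccccc21
FIX033,anthracene,c1ccc2cc3ccccc3cc2c1
FIX034,phenanthrene,c1ccc2ccc3ccccc3c2c1
FIX035,fluoranthene,c1ccc2c(c1)-c1cccc3cccc2c13
FIX036,pyrene,c1cc2ccc3cccc4ccc(c1)c2c34
FIX037,benzo[a]anthracene,c1ccc2c(c1)ccc1cc3ccccc3cc12
FIX038,chrysene,c1ccc2c(c1)ccc1c2ccc2ccccc21
FIX039,benzo[a]pyrene,c1cc2ccc3ccc4c5ccccc5cc5ccc(c1)c2c3c45
FIX040,toluene,Cc1ccccc1
FIX041,o-xylene,Cc1ccccc1C
FIX042,m-xylene,Cc1cccc(C)c1
FIX043,p-xylene,Cc1ccc(C)cc1
FIX044,ethylbenzene,CCc1ccccc1
FIX045,styrene,C=Cc1ccccc1
FIX046,pentane,CCCCC
FIX047,hexane,CCCCCC
FIX048,heptane,CCCCCCC
FIX049,octane,CCCCCCCC
FIX050,nonane,CCCCCCCCC
FIX051,decane,CCCCCCCCCC
FIX052,undecane,CCCCCCCCCCC
FIX053,dodecane,CCCCCCCCCCCC
FIX054,2-methylpentane,CCCC(C)C
FIX055,"2,2,4-trimethylpentane",CC(C)CC(C)(C)C
FIX056,cyclohexane,C1CCCCC1
FIX057,methylcyclohexane,CC1CCCCC1
FIX058,methanol,CO
FIX059,ethanol,CCO
FIX060,1-propanol,CCCO
FIX061,2-propanol,CC(C)O
FIX062,1-butanol,CCCCO
FIX063,1-pentanol,CCCCCO
FIX064,1-hexanol,CCCCCCO
FIX065,1-octanol,CCCCCCCCO
FIX066,1-decanol,CCCCCCCCCCO
FIX067,cyclohexanol,OC1CCCCC1
FIX068,benzyl alcohol,OCc1ccccc1
FIX069,2-phenylethanol,OCCc1ccccc1
FIX070,methyl acetate,CC(=O)OC
FIX071,ethyl acetate,CC(=O)OCC
FIX072,propyl acetate,CC(=O)OCCC
FIX073,butyl acetate,CC(=O)OCCCC
FIX074,ethyl propanoate,CCOC(=O)CC
FIX075,methyl benzoate,COC(=O)c1ccccc1
FIX076,ethyl benzoate,CCOC(=O)c1ccccc1
FIX077,dimethyl phthalate,COC(=O)c1ccccc1C(=O)OC
FIX078,diethyl phthalate,CCOC(=O)c1ccccc1C(=O)OCC
FIX079,dibutyl phthalate,CCCCOC(=O)c1ccccc1C(=O)OCCCC
FIX080,methyl salicylate,COC(=O)c1ccccc1O
FIX081,ethyl hexanoate,CCCCCC(=O)OCC
FIX082,phenol,Oc1ccccc1
FIX083,o-cresol,Cc1ccccc1O
FIX084,m-cresol,Cc1cccc(O)c1
FIX085,p-cresol,Cc1ccc(O)cc1
FIX086,2-chlorophenol,Oc1ccccc1Cl
FIX087,4-chlorophenol,Oc1ccc(Cl)cc1
FIX088,"2,4-dichlorophenol",Oc1ccc(Cl)cc1Cl
FIX089,pentachlorophenol,Oc1c(Cl)c(Cl)c(Cl)c(Cl)c1Cl
FIX090,diethyl ether,CCOCC
FIX091,dibutyl ether,CCCCOCCCC
FIX092,anisole,COc1ccccc1
FIX093,diphenyl ether,c1ccc(Oc2ccccc2)cc1
FIX094,tetrahydrofuran,C1CCOC1
FIX095,"1,4-dioxane",C1COCCO1
FIX096,acetone,CC(C)=O
FIX097,2-butanone,CCC(C)=O
FIX098,2-hexanone,CCCCC(C)=O
FIX099,cyclohexanone,O=C1CCCCC1
FIX100,acetophenone,CC(=O)c1ccccc1
FIX101,benzaldehyde,O=Cc1ccccc1
FIX102,hexanal,CCCCCC=O
FIX103,octanal,CCCCCCCC=O
FIX104,trichloromethane,ClC(Cl)Cl
FIX105,tetrachloromethane,ClC(Cl)(Cl)Cl
FIX106,"1,2-dichloroethane",ClCCCl
FIX107,trichloroethene,ClC=C(Cl)Cl
FIX108,tetrachloroethene,ClC(Cl)=C(Cl)Cl
FIX109,"1,1,1-trichloroethane",CC(Cl)(Cl)Cl
FIX110,lindane,ClC1C(Cl)C(Cl)C(Cl)C(Cl)C1Cl
FIX111,alpha-HCH,ClC1C(Cl)C(Cl)C(Cl)C(Cl)C1Cl
FIX112,"p,p'-DDT",Clc1ccc(C(c2ccc(Cl)cc2)C(Cl)(Cl)Cl)cc1
FIX113,"p,p'-DDE",Clc1ccc(C(=C(Cl)Cl)c2ccc(Cl)cc2)cc1
FIX114,naphthalen1ol,Oc1cccc2ccccc12
FIX115,nitrobenzene,O=[N+]([O-])c1ccccc1
FIX116,aniline,Nc1ccccc1
FIX117,benzonitrile,N#Cc1ccccc1
FIX118,quinoline,c1ccc2ncccc2c1
FIX119,dibenzofuran,c1ccc2c(c1)oc1ccccc12
FIX120,dibenzodioxin,c1ccc2c(c1)Oc1ccccc1O2
FIX121,"2,3,7,8-TCDD",Clc1cc2Oc3cc(Cl)c(Cl)cc3Oc2cc1Cl
FIX122,atrazine,CCNc1nc(Cl)nc(NC(C)C)n1
FIX123,gamma-terpinene,CC(C)C1=CCC(C)=CC1
FIX124,limonene,CC(=C)C1CCC(C)=CC1
FIX125,alpha-pinene,CC1=CCC2CC1C2(C)C
FIX126,n-propylbenzene,CCCc1ccccc1
FIX127,naphthalene2amine,Nc1ccc2ccccc2c1
FIX128,carbazole,c1ccc2c(c1)[nH]c1ccccc12
FIX129,benzothiophene,c1ccc2sccc2c1
FIX130,thiophene,c1ccsc1
FIX131,dimethyl sulfide,CSC
FIX132,methyl tert-butyl ether,COC(C)(C)C
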