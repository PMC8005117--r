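ligand_name,ligand_id,kinase_name,pdb_id,resolution
inhibitor-ibr-1,IBR,ABL1,372C,2.71
inhibitor-lev-2,LEV,BTK,3C03,1.98
inhibitor-st1-3,ST1,BTK,48DC,1.29
inhibitor-st2-4,ST2,SRC,82FE,2.25
inhibitor-qz3-5,QZ3,ABL1,2907,2.7
inhibitor-qz3-6,QZ3,AURKA,27FA,1.93
inhibitor-qz3-7,QZ3,EGFR,9765,1.13
inhibitor-atp-8,ATP,CDK2,59B7,1.85
inhibitor-adp-9,ADP,CDK2,9D4F,2.02
inhibitor-mg-10,MG,ABL1,2A45,1.09
inhibitor-gol-11,GOL,AURKA,9F70,1.9
inhibitor-pk1-12,PK1,CDK2,7EFB,1.86
inhibitor-pk2-13,PK2,VEGFR2,24B2,2.41
inhibitor-pk3-14,PK3,VEGFR2,5B16,1.08
inhibitor-pk4-15,PK4,EGFR,5500,1.2
inhibitor-pk5-16,PK5,AURKA,4D10,2.93
inhibitor-pk5-17,PK5,ABL1,1E53,1.01
inhibitor-xn1-18,XN1,SRC,8C65,1.35
inhibitor-xn2-19,XN2,BTK,9B64,2.12
inhibitor-xn3-20,XN3,CDK2,3270,2.23
inhibitor-so4-21,SO4,VEGFR2,9722,1.74
inhibitor-edo-22,EDO,SRC,7893,2.54
inhibitor-hh1-23,HH1,VEGFR2,4DCE,1.63
inhibitor-hh2-24,HH2,SRC,9BB0,2.1
inhibitor-hh3-25,HH3,VEGFR2,6267,2.41
inhibitor-hh4-26,HH4,ABL1,4B14,3
inhibitor-ibr-27,IBR,ABL1,9D34,1.16
inhibitor-lev-28,LEV,CDK2,1DA3,1.44
inhibitor-pk1-29,PK1,ABL1,8454,2.4
inhibitor-hh5-30,HH5,EGFR,68AC,2.48
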