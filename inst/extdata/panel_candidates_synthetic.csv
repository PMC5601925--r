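antigen_id,peptide,category
mLama4,VGFNFRTL,known
mAlg8,ITYTWTRL,known
cand01,NMFWFHDM,predicted
cand02,TPMLYHFV,predicted
cand03,DFLEYTQV,predicted
cand04,YSNWFVTM,predicted
cand05,HQAGYFAL,predicted
cand06,LKDVYHDV,predicted
cand07,HKYLYFMM,predicted
cand08,PPRMYYWM,predicted
cand09,SKAIYFWL,predicted
cand10,TVCTYEHV,predicted
cand11,IRLQFMYL,predicted
cand12,WIFVYVHV,predicted
cand13,EPEKFFTV,predicted
cand14,PYIAYIRL,predicted
cand15,ESCIFDPM,predicted
cand16,KWMFFPWV,predicted
cand17,HAFEFYMV,predicted
cand18,PILTFAMV,predicted
cand19,PNQIYQYL,predicted
cand20,DSHDYKQL,predicted
cand21,SCFQYWEM,predicted
cand22,KHFYYCQL,predicted
cand23,LVYCFMLL,predicted
cand24,GHYMFFGL,predicted
cand25,NHFQFLNL,predicted
cand26,QHAAYLKL,predicted
cand27,KDHFYIML,predicted
cand28,QCCRFACM,predicted
cand29,VKDAYHKM,predicted
cand30,KFMEYPDL,predicted
cand31,VIRGYQCL,predicted
cand32,DQSFFEFM,predicted
cand33,LYGAFWKV,predicted
cand34,FKWAYIFV,predicted
cand35,PWECYNCL,predicted
cand36,KIVRFGVL,predicted
cand37,NYGWYSNM,predicted
cand38,TPKAFEFV,predicted
cand39,PGTKFYEL,predicted
cand40,LVNFFCPL,predicted
cand41,DYQQYSPL,predicted
cand42,AAFSFMDL,predicted
cand43,HPWTFQYV,predicted
cand44,HEAGFAPM,predicted
cand45,GGEAYAGM,predicted
cand46,WGHAYMEM,predicted
cand47,ALEFYLQM,predicted
cand48,LRASFDVM,predicted
cand49,GPLMYHTV,predicted
cand50,YSWNYMHL,predicted
cand51,EALRYYYV,predicted
cand52,KTLTFVQM,predicted
cand53,SEEIFHCM,predicted
cand54,SNCCYMHV,predicted
cand55,AGGRYRDM,predicted
cand56,WQWKYLGL,predicted
cand57,KYHKFAPL,predicted
cand58,PIYNYPHM,predicted
cand59,IHPTFEFM,predicted
cand60,YTSSYEPV,predicted
cand61,THFWYHRM,predicted
cand62,ARRCYINV,predicted
cand63,YDDVFPLL,predicted
cand64,TWIHFGQV,predicted
cand65,AKLRYHAV,predicted
cand66,ELNDYSNL,predicted
cand67,TNWGYWAL,predicted
cand68,FPMSYMRL,predicted
cand69,PPKRYFLL,predicted
cand70,MLPRFWIM,predicted
cand71,SDLYYMCV,predicted
cand72,FPKIFYAV,predicted
cand73,CAGYFTNV,predicted
cand74,RDKYYPHV,predicted
cand75,DFRIFDCM,predicted
cand76,CMPIFFKL,predicted
cand77,LMEKFSMM,predicted
cand78,QTNNFQDL,predicted
cand79,HTNQYYYL,predicted
SIINFEKL,SIINFEKL,control
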