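"id","smiles"
"aspirin","CC(=O)Oc1ccccc1C(=O)O"
"paracetamol","CC(=O)Nc1ccc(O)cc1"
"ibuprofen","CC(C)Cc1ccc(cc1)C(C)C(=O)O"
"caffeine","Cn1cnc2c1c(=O)n(C)c(=O)n2C"
"nicotine","CN1CCCC1c1cccnc1"
"benzocaine","CCOC(=O)c1ccc(N)cc1"
"procaine","CCN(CC)CCOC(=O)c1ccc(N)cc1"
"lidocaine","CCN(CC)CC(=O)Nc1c(C)cccc1C"
"ethosuximide","CCC1(C)CC(=O)NC1=O"
"valproate","CCCC(CCC)C(=O)O"
"deet","CCN(CC)C(=O)c1cccc(C)c1"
"phenacetin","CCOc1ccc(NC(C)=O)cc1"
"salicylamide","NC(=O)c1ccccc1O"
"benzamide","NC(=O)c1ccccc1"
"gaba","NCCCC(=O)O"
"putrescine_amide","NCCCCNC(C)=O"
"levulinic","CC(=O)CCC(=O)O"
"propranolol_core","CC(C)NCC(O)COc1ccccc1"
"synth_01","CCNC(C)=O"
"synth_02","CCCNC(C)=O"
"synth_03","CCNC(=O)CC"
"synth_04","CCCNC(=O)CC"
"synth_05","CCNC(=O)C(C)C"
"synth_06","CCCNC(=O)C(C)C"
"synth_07","CCNC(=O)c1ccccc1"
"synth_08","CCCNC(=O)c1ccccc1"
"synth_09","OCCNC(C)=O"
"synth_10","OCCNC(=O)CC"
"synth_11","OCCNC(=O)c1ccccc1"
"synth_12","C1CCCCC1NC(C)=O"
"synth_13","C1CCCCC1NC(=O)CC"
"synth_14","c1ccccc1NC(C)=O"
"synth_15","c1ccccc1NC(=O)CC"
"synth_16","c1ccccc1CCNC(C)=O"
"synth_17","c1ccccc1CCNC(=O)CC"
"synth_18","CCOC(=O)CC"
"synth_19","CCOC(=O)C(C)C"
"synth_20","CCOC(=O)c1ccccc1"
"synth_21","CCCOC(C)=O"
"synth_22","CCOCC"
"synth_23","CCOCCC"
"synth_24","CCCOCCO"
"synth_25","CCN(C)CC"
"synth_26","CCCN(C)C"
"synth_27","c1ccccc1CN(C)C"
"synth_28","CCNCCO"
"synth_29","CC(C)NC(=O)C1CCCC1"
"synth_30","CCNC(=O)Cc1ccco1"
"synth_31","OCCNC(=O)C(C)C"
"synth_32","CCCCNC(=O)CC"
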