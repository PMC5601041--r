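Fp1	-0.2938926261	0.9045084972	0.3090169944
Fpz	0.0000000000	0.9510565163	0.3090169944
Fp2	0.2938926261	0.9045084972	0.3090169944
AF7	-0.5590169944	0.7694208843	0.3090169944
AF3	-0.3129614967	0.7985590319	0.5141581217
AF4	0.3129614967	0.7985590319	0.5141581217
AF8	0.5590169944	0.7694208843	0.3090169944
F7	-0.7694208843	0.5590169944	0.3090169944
F5	-0.6407066077	0.5707833100	0.5135187006
F3	-0.4590305300	0.5799596819	0.6730064932
F1	-0.2394102773	0.5857875770	0.7742968641
Fz	0.0000000000	0.5877852523	0.8090169944
F2	0.2394102773	0.5857875770	0.7742968641
F4	0.4590305300	0.5799596819	0.6730064932
F6	0.6407066077	0.5707833100	0.5135187006
F8	0.7694208843	0.5590169944	0.3090169944
FT7	-0.9045084972	0.2938926261	0.3090169944
FC5	-0.7657841515	0.3000129629	0.5688293729
FC3	-0.5546573527	0.3048513645	0.7742227500
FC1	-0.2910894675	0.3079503756	0.9057778360
FC2	0.2910894675	0.3079503756	0.9057778360
FC4	0.5546573527	0.3048513645	0.7742227500
FC6	0.7657841515	0.3000129629	0.5688293729
FT8	0.9045084972	0.2938926261	0.3090169944
T7	-0.9510565163	0.0000000000	0.3090169944
C5	-0.8090169944	0.0000000000	0.5877852523
C3	-0.5877852523	0.0000000000	0.8090169944
C1	-0.3090169944	0.0000000000	0.9510565163
Cz	0.0000000000	0.0000000000	1.0000000000
C2	0.3090169944	0.0000000000	0.9510565163
C4	0.5877852523	0.0000000000	0.8090169944
C6	0.8090169944	0.0000000000	0.5877852523
T8	0.9510565163	0.0000000000	0.3090169944
TP7	-0.9045084972	-0.2938926261	0.3090169944
CP5	-0.7657841515	-0.3000129629	0.5688293729
CP3	-0.5546573527	-0.3048513645	0.7742227500
CP1	-0.2910894675	-0.3079503756	0.9057778360
CPz	0.0000000000	-0.3090169944	0.9510565163
CP2	0.2910894675	-0.3079503756	0.9057778360
CP4	0.5546573527	-0.3048513645	0.7742227500
CP6	0.7657841515	-0.3000129629	0.5688293729
TP8	0.9045084972	-0.2938926261	0.3090169944
P7	-0.7694208843	-0.5590169944	0.3090169944
P5	-0.6407066077	-0.5707833100	0.5135187006
P3	-0.4590305300	-0.5799596819	0.6730064932
P1	-0.2394102773	-0.5857875770	0.7742968641
Pz	0.0000000000	-0.5877852523	0.8090169944
P2	0.2394102773	-0.5857875770	0.7742968641
P4	0.4590305300	-0.5799596819	0.6730064932
P6	0.6407066077	-0.5707833100	0.5135187006
P8	0.7694208843	-0.5590169944	0.3090169944
PO7	-0.5590169944	-0.7694208843	0.3090169944
PO3	-0.3129614967	-0.7985590319	0.5141581217
POz	0.0000000000	-0.8090169944	0.5877852523
PO4	0.3129614967	-0.7985590319	0.5141581217
PO8	0.5590169944	-0.7694208843	0.3090169944
O1	-0.2938926261	-0.9045084972	0.3090169944
Oz	-0.0000000000	-0.9510565163	0.3090169944
O2	0.2938926261	-0.9045084972	0.3090169944
TP9	-0.9045084972	-0.2938926261	-0.3090169944
TP10	0.9045084972	-0.2938926261	-0.3090169944
VEOG	-0.2461515394	0.9186500513	-0.3090169944
HEOG	0.5679944299	0.8111801129	-0.1391731010
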