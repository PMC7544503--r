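cell,timepoints,percent
'AIAL',0,0.0
'AIAR',0,0.0
'AIML',0,0.0
'AIMR',0,0.0
'AINL',35,53.8
'AINR',56,86.2
'AIYL',39,60.0
'AIYR',40,61.5
'ALA',0,0.0
'AVAL',0,0.0
'AVAR',0,0.0
'AVDL',65,100.0
'AVDR',34,52.3
'AVEL',0,0.0
'AVER',0,0.0
'AVG',51,78.5
'AVHL',65,100.0
'AVHR',54,83.1
'AVJL',0,0.0
'AVJR',0,0.0
'AVKL',37,56.9
'AVKR',0,0.0
'AVL',33,50.8
'BAGL',32,49.2
'BAGR',42,64.6
'CEPDL',26,40.0
'CEPDR',31,47.7
'CEPVL',0,0.0
'CEPVR',0,0.0
'IL1DL',19,29.2
'IL1DR',19,29.2
'IL1L',0,0.0
'IL1R',42,64.6
'IL1VL',0,0.0
'IL1VR',0,0.0
'IL2DL',36,55.4
'IL2DR',27,41.5
'IL2L',0,0.0
'IL2R',0,0.0
'IL2VL',0,0.0
'IL2VR',0,0.0
'OLLL',0,0.0
'OLLR',0,0.0
'OLQDL',63,96.9
'OLQDR',65,100.0
'OLQVL',0,0.0
'OLQVR',0,0.0
'RIAL',0,0.0
'RIAR',32,49.2
'RID',16,24.6
'RIFL',0,0.0
'RIFR',0,0.0
'RIGL',0,0.0
'RIGR',0,0.0
'RIH',27,41.5
'RIPL',54,83.1
'RIPR',0,0.0
'RIR',41,63.1
'RIS',59,90.8
'RIVL',65,100.0
'RIVR',0,0.0
'RMDDL',22,33.8
'RMDDR',16,24.6
'RMDL',0,0.0
'RMDR',0,0.0
'RMDVL',0,0.0
'RMDVR',18,27.7
'RMED',16,24.6
'RMEL',41,63.1
'RMER',54,83.1
'RMEV',65,100.0
'RMGL',0,0.0
'RMGR',0,0.0
'SAADL',0,0.0
'SAADR',7,10.8
'SAAVL',43,66.2
'SAAVR',18,27.7
'SABD',0,0.0
'SABVL',0,0.0
'SABVR',0,0.0
'SIADL',7,10.8
'SIADR',23,35.4
'SIAVL',51,78.5
'SIAVR',18,27.7
'SIBVL',0,0.0
'SIBVR',2,3.1
'SMBDL',11,16.9
'SMBDR',17,26.2
'SMBVL',0,0.0
'SMBVR',0,0.0
'SMDDL',65,100.0
'SMDDR',53,81.5
'SMDVL',52,80.0
'SMDVR',10,15.4
'URAVL',0,0.0
'URAVR',0,0.0
'URADL',0,0.0
'URADR',0,0.0
'URBL',0,0.0
'URBR',0,0.0
'URXL',26,40.0
'URXR',31,47.7
'URYDL',13,20.0
'URYDR',44,67.7
'URYVL',0,0.0
'URYVR',0,0.0
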