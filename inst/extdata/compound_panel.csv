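id,name,class,conc_g_per_L,molar_mass_Da,logP,TPSA_nm2,HBd
La,lacosamide,anti-convulsant,8.3e-3,250,-0.02,0.674,2
Li,licarbazepine,anti-convulsant,2.9e-2,254,1.73,0.666,2
Ru,rufinamide,anti-convulsant,2.5e-2,238,1.27,0.738,1
Zo,zonisamide,anti-convulsant,3.3e-2,212,0.11,0.862,1
Am,amitriptyline,anti-depressant,1.7e-4,277,4.81,0.032,0
Ci,citalopram,anti-depressant,9.2e-5,324,3.76,0.363,0
Cl,clomipramine,anti-depressant,3.8e-4,315,4.88,0.065,0
Fl,fluoxetine,anti-depressant,4.2e-4,309,4.17,0.213,1
No,nortriptyline,anti-depressant,1.4e-4,263,4.43,0.120,1
Se,sertraline,anti-depressant,1.3e-4,306,5.15,0.120,1
Vo,vortioxetine,anti-depressant,3.3e-5,298,4.76,0.153,1
Ha,haloperidol,anti-psychotic,8.3e-6,376,3.66,0.405,1
Pa,paliperidone,anti-psychotic,5.0e-5,426,1.76,0.822,1
Ri,risperidone,anti-psychotic,5.0e-5,410,2.63,0.619,0
Me,methadone,anti-addictive,5.0e-4,309,5.01,0.203,0
F*,fluorescein,fluorophore,2.8e-4,330,3.01,0.895,0
N*,Nile blue,fluorophore,2.7e-4,318,3.85,0.504,1
T*,TAMRA,fluorophore,3.6e-4,430,-0.29,0.929,1
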