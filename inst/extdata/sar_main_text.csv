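id,parent,field,value,comparator,units,provenance
masitinib,,delta_tm,7.4,,C,campaign main text: TSA panel (first derivatives)
masitinib,,kd,1400,,nM,campaign main text: ITC (1.4 uM dissociation constant)
masitinib,,selectivity_ratio_il3_scf,100,>,ratio,campaign main text: c-KIT counterscreen
dCKi1,masitinib,delta_tm,14.3,,C,campaign main text: TSA panel
dCKi1,masitinib,kd,128,,nM,campaign main text: ITC
dCKi1,masitinib,cellular_ic50,6900,,nM,campaign main text: CCRF-CEM proliferation (dT+dC)
dCKi1,masitinib,selectivity_ratio_il3_scf,7.6,,ratio,campaign main text: c-KIT counterscreen
dCKi2,,delta_tm,17.3,,C,campaign main text: TSA panel
dCKi2,,kd,37,,nM,campaign main text: ITC
dCKi2,,cellular_ic50,8900,,nM,campaign main text: CCRF-CEM proliferation (dT+dC)
dCKi2,,selectivity_ratio_il3_scf,2.7,,ratio,campaign main text: c-KIT counterscreen
OR0274,dCKi1,delta_tm,16.7,,C,campaign main text: biphenyl C-D linker suppression
OR0274,dCKi1,cellular_ic50,2096,,nM,campaign main text: biphenyl C-D linker suppression
OR0325,OR0274,delta_tm,17.8,,C,campaign main text: D-E linker elongation
OR0325,OR0274,cellular_ic50,1676,,nM,campaign main text: D-E linker elongation
OR0345,OR0325,delta_tm,18.4,,C,campaign main text: N-propyl on B-C linker
OR0345,OR0325,cellular_ic50,505,,nM,campaign main text: N-propyl on B-C linker
OR0600,OR0345,delta_tm,20.0,,C,campaign main text: fusion analog of the two series
OR0600,OR0345,cellular_ic50,341,,nM,campaign main text: fusion analog of the two series
OR0602,OR0600,cellular_ic50,130,,nM,campaign main text: ring D pyridine
OR0602,OR0600,enzymatic_ic50,77,,nM,campaign main text: ring D pyridine (at technical limit)
OR0624,OR0600,cellular_ic50,46,,nM,campaign main text: sulfonamide D-E linker
OR0634,OR0602,cellular_ic50,54,,nM,campaign main text: hybrid of ring-D pyridine and sulfonamide
OR0635,OR0634,delta_tm,20.4,,C,campaign main text: ring D OMe substitution
OR0635,OR0634,cellular_ic50,15,,nM,campaign main text: ring D OMe substitution
OR0642,OR0634,delta_tm,22.2,,C,campaign main text: ring D CF3 substitution (lead)
OR0642,OR0634,cellular_ic50,2.2,,nM,campaign main text: ring D CF3 substitution (lead)
OR0659,,delta_tm,6.3,,C,campaign main text: negative control analog
OR0659,,enzymatic_ic50,100000,>,nM,campaign main text: negative control analog
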