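condition,coulomb_kJ_mol,sd_coulomb_kJ_mol,lj_kJ_mol,sd_lj_kJ_mol,total_kJ_mol,sd_total_kJ_mol
WT,-14.50,1.76,-101.39,27.43,-115.89,29.19
L89W,-14.77,3.90,-192.48,3.39,-207.25,7.29
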