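wavenumber,tissue,assignment
4092.21,BFL,C-H aryl vibration in benzene band
4096.06,BFL,C-H aryl vibration in benzene band
4123.06,FLP,C-H aryl vibration in benzene band
4165.49,BFL,C-H aryl vibration in benzene band
4308.19,BFL,combination of C-H stretch and C-H2 deformation in polysaccharides
4439.33,BFL,combination of O-H and C-O stretch in glucose
4485.61,BFL,second overtones of symmetric and asymmetric CH2 bending of the uncoupled vinyl group
4501.04,BFL,combination of asymmetric N-H stretch and NH2 rocking in urea
4508.75,FLP,combination of asymmetric N-H stretch and NH2 rocking in urea
4566.61,BFL,C-H aryl vibration in benzene band
4570.47,BFL,C-H aryl vibration in benzene band
4597.46,BFL,CONH2 combination of amide B and amide II modes
4612.89,BFL,CONH2 of the alpha-helix peptide structure
4952.30,FLP,combination of O-H stretch and C-H bending
5079.58,BFL,combination of N-H stretching and N-H bending in aromatic amine
5230.00,FLP,hydroxyl band
5233.86,FLP,hydroxyl band
5303.28,FLP,hydroxyl band
5634.98,FLP,C-H in methylene
5685.12,FLP,C-H in methylene
5866.40,BFL,C-H first overtone stretch in CH3
5874.11,FLP,C-H in methyl
5928.11,FLP,C-H in methyl with associated O-H
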