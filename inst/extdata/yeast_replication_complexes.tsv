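# yeast Shu complex and replication-initiation complexes (standard memberships)
SHU	Csm2,Psy3,Shu1,Shu2
CMG	Cdc45,Mcm2,Mcm3,Mcm4,Mcm5,Mcm6,Mcm7,Sld5,Psf1,Psf2,Psf3
MCM	Mcm2,Mcm3,Mcm4,Mcm5,Mcm6,Mcm7
ORC	Orc1,Orc2,Orc3,Orc4,Orc5,Orc6
GINS	Sld5,Psf1,Psf2,Psf3
MTC	Mrc1,Tof1,Csm3
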