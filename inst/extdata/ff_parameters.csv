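section,name,mass,p1,p2,p3,p4,note
lj,CH4,16.04246,158.5,3.72,,,united-atom alkane LJ (eps/kB K; sigma A) after Dubbeldam et al.
lj,CH3,15.03452,108.0,3.76,,,
lj,CH2,14.02658,56.0,3.96,,,
lj,CH,13.01864,17.0,4.67,,,
lj,C,12.0107,0.8,6.38,,,
lj,Si,28.0855,22.0,2.30,,,TraPPE-zeo zeolite silicon
lj,O,15.9994,53.0,3.30,,,TraPPE-zeo zeolite oxygen
bond,HARMONIC_BOND,,96500,1.54,,,k/kB K/A^2; r0 A
bend,HARMONIC_BEND,,62500,114.0,,,k/kB K/rad^2; theta0 deg
torsion,TRAPPE_DIHEDRAL,,0.0,355.03,-68.19,791.32,cosine-series constants c0..c3 in K
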