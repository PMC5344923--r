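# Bacterial immunity protein Im7 (86 residues, PDB 1AYI numbering); protection factors characterize the on-pathway folding intermediate. Values are ln P.
residue,resname,value,log_base
9,ASP,8,ln
10,TYR,9.2,ln
11,THR,10.2,ln
16,VAL,11.5,ln
17,GLN,11.6,ln
18,LEU,11.2,ln
21,GLU,8.5,ln
23,GLU,6,ln
37,LEU,6.1,ln
38,LEU,7.5,ln
41,PHE,6,ln
42,VAL,10.3,ln
53,LEU,3.5,ln
54,ILE,3.6,ln
55,TYR,4.4,ln
56,TYR,5.6,ln
67,GLY,8.1,ln
69,VAL,8.8,ln
72,ILE,9,ln
73,LYS,9.5,ln
74,GLU,9,ln
75,TRP,8.8,ln
76,ARG,9.9,ln
77,ALA,9.8,ln
78,ALA,8,ln
85,LYS,6.8,ln
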