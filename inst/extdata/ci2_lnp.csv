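# Truncated chymotrypsin inhibitor 2 (64 residues, PDB 1TM1 numbering); residue 1 corresponds to residue 20 of the full protein. Values are ln P.
residue,resname,value,log_base
8,LEU,8.1,ln
9,VAL,9.9,ln
13,VAL,7.2,ln
16,ALA,7.1,ln
17,LYS,6.6,ln
18,LYS,8.2,ln
22,GLN,9.5,ln
27,ALA,6.7,ln
28,GLN,8.2,ln
52,ASP,8.5,ln
56,ASN,8.4,ln
58,ALA,9,ln
59,GLN,10.5,ln
63,VAL,7.4,ln
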