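substance,ddd_mg_per_kg,substance_class,long_acting_factor
colistin,5,polypeptides,
ceftiofur,3,cephalosporins,
amoxicillin,20,penicillins,
benzylpenicillin,10,penicillins,2
enrofloxacin,2.5,fluoroquinolones,
gentamicin,4,aminoglycosides,
tylosin,10,macrolides,
chlortetracycline,20,tetracyclines,
doxycycline,10,tetracyclines,
trimethoprim,4,trimethoprim,
sulfadimidine,20,sulfonamides,
tiamulin,10,pleuromutilins,
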