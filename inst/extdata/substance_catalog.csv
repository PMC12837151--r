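substance_code,ab_class,is_critical,carryover_days
amoxicillin,penicillin,FALSE,0
ampicillin,penicillin,FALSE,0
trimethoprim,trimethoprim,FALSE,0
sulfadiazine,sulfonamide,FALSE,0
doxycycline,tetracycline,FALSE,0
clindamycin,lincosamide,FALSE,0
cefalexin,cephalosporin_1g,FALSE,0
gentamicin,aminoglycoside,FALSE,0
metronidazole,nitroimidazole,FALSE,0
enrofloxacin,fluoroquinolone,TRUE,0
marbofloxacin,fluoroquinolone,TRUE,0
pradofloxacin,fluoroquinolone,TRUE,0
azithromycin,macrolide,TRUE,0
erythromycin,macrolide,TRUE,0
cefovecin,cephalosporin_3g,TRUE,13
cefquinome,cephalosporin_4g,TRUE,0
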