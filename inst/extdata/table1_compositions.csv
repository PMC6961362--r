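label,composition,n_products,note
Highest priority+High priority,colistin|amoxicillin,12,
Highest priority+High priority,colistin|ampicillin,12,
Highest priority+High priority,colistin|neomycin,8,
Highest priority+High priority,colistin|gentamicin,2,
Highest priority+High priority,colistin|apramycin,1,
Highest priority+High priority,tylosin|gentamicin,5,
Highest priority+High priority,tylosin|amoxicillin,2,
Highest priority+High priority,tylosin|streptomycin,1,
Highest priority only,enrofloxacin,12,
Highest priority only,flumequine,9,
Highest priority only,tilmicosin,6,
Highest priority only,erythromycin,2,
Highest priority only,norfloxacin,2,
Highest priority only,tylosin,1,
Highest priority only,colistin,2,
Highest priority only,colistin|tylosin,3,
Highest priority only,colistin|spiramycin,2,
Highest priority only,colistin|enrofloxacin,1,
Highest priority only,colistin|erythromycin,1,
Highest priority+Highly important,colistin|oxytetracycline,9,printed count 8; one product added so the row totals its printed 38 (the printed composition counts of this row sum to 37)
Highest priority+Highly important,colistin|doxycycline,1,
Highest priority+Highly important,colistin|lincomycin,1,
Highest priority+Highly important,colistin|sulfadimethoxine,1,
Highest priority+Highly important,doxycycline|tylosin,6,
Highest priority+Highly important,doxycyline|tilmicosin,1,
Highest priority+Highly important,erythromycin|sulphamethoxazole,2,
Highest priority+Highly important,erythromycin|oxytetracycline,1,
Highest priority+Highly important,kitasamycin|thiamphenicol,1,
Highest priority+Highly important,oxytetracycline|neomycine,2,
Highest priority+Highly important,oxytetracycline|spiramycin,3,
Highest priority+Highly important,oxytetracycline|tylosin,2,
Highest priority+Highly important,tylosin|sulfadimidine,3,
Highest priority+Highly important,tylosin|tetracycline,2,
Highest priority+Highly important,tylosin|sulfachloropyridazine,1,
Highest priority+Highly important,tylosin|sulfamethazine,1,
Highest priority+Highly important,tylosin|sulphamethoxazole,1,
Highly important only,oxytetracycline,9,
Highly important only,oxytetracycline|sulfadimidine,1,
Highly important only,oxytetracycline|thiamphenicol,1,
Highly important only,doxycycline,5,
Highly important only,doxycycline|florfenicol,3,
Highly important only,doxycycline|lincomycin,1,
Highly important only,florfenicol,8,
Highly important only,lincomycin,2,
Highly important only,cephalexin,1,
Highly important only,cefadroxil,1,
Highly important only,sulphathiazole,1,
Highly important only,sulfamethoxypyridazine|tetracycline,1,
Highly important only,sulphamethoxazole|thiamphenicol,1,
High priority+Highly important,lincomycin|spectinomycin,6,
High priority+Highly important,doxycycline|gentamicin,5,
High priority+Highly important,doxycycline|neomycin,1,
High priority+Highly important,doxycycline|ampicillin,1,
High priority+Highly important,oxytetracycline|streptomycin,5,
High priority+Highly important,oxytetracycline|neomycin,4,
High priority+Highly important,ampicillin|sulfadimethoxine,1,
High priority+Highly important,gentamicin|sulfadimidine,1,
High priority+Highly important,streptomycin|sulphamethoxazole,1,
High priority only,amoxicillin,7,
High priority only,neomycin,3,
High priority only,ampicillin,1,
High priority only,streptomycin,1,
Highly important+Other,sulfadimethoxine|trimethoprim,4,
Highly important+Other,sulfadiazine|trimethoprim,1,
Highly important+Other,sulfadimidine|trimethoprim,1,
Highly important+Other,sulphamethoxazole|trimethoprim,1,
Highly important+Other,doxycycline|tiamulin,1,
Highest priority+Other,colistin|trimethoprim,3,
Highest priority+Other,josamycin|trimethoprim,1,
Highest priority+Other,spiramycin|trimethoprim,1,
Highest priority+Other,colistin|enramycin,1,
Other only,trimethoprim,2,
Other only,methenamine,1,
High priority+Other,gentamicin|trimethoprim,1,
High priority+Other,neomycin|trimethoprim,1,
Highest priority+Highly important+Other,tylosin|trimethoprim|sulfadiazine|sulphamethoxazole,1,
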