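name,alias,who_category,aai_class,note
colistin,,HIGHEST_PRIORITY,polymyxin,
tylosin,,HIGHEST_PRIORITY,macrolide,
tilmicosin,,HIGHEST_PRIORITY,macrolide,
erythromycin,,HIGHEST_PRIORITY,macrolide,
spiramycin,spiramycine,HIGHEST_PRIORITY,macrolide,
kitasamycin,,HIGHEST_PRIORITY,macrolide,
josamycin,josamycine,HIGHEST_PRIORITY,macrolide,
enrofloxacin,,HIGHEST_PRIORITY,quinolone,
flumequine,,HIGHEST_PRIORITY,quinolone,
norfloxacin,,HIGHEST_PRIORITY,quinolone,
neomycine,,HIGHEST_PRIORITY,aminoglycoside,transcribed spelling kept distinct from neomycin: the source catalogue groups products with this spelling under highest-priority combinations
amoxicillin,amoxycillin,HIGH_PRIORITY,penicillin,
ampicillin,,HIGH_PRIORITY,penicillin,
neomycin,,HIGH_PRIORITY,aminoglycoside,
gentamicin,gentamycin,HIGH_PRIORITY,aminoglycoside,
apramycin,,HIGH_PRIORITY,aminoglycoside,
streptomycin,,HIGH_PRIORITY,aminoglycoside,
spectinomycin,,HIGH_PRIORITY,aminocyclitol,
oxytetracycline,,HIGHLY_IMPORTANT,tetracycline,
doxycycline,doxycyline,HIGHLY_IMPORTANT,tetracycline,
tetracycline,,HIGHLY_IMPORTANT,tetracycline,
lincomycin,,HIGHLY_IMPORTANT,lincosamide,
cephalexin,cefalexin,HIGHLY_IMPORTANT,cephalosporin,
cefadroxil,,HIGHLY_IMPORTANT,cephalosporin,
thiamphenicol,,HIGHLY_IMPORTANT,amphenicol,
florfenicol,,HIGHLY_IMPORTANT,amphenicol,
sulfamethoxazole,sulphamethoxazole,HIGHLY_IMPORTANT,sulfonamide,
sulfadimethoxine,sulphadimethoxine,HIGHLY_IMPORTANT,sulfonamide,
sulfadimidine,sulphadimidine,HIGHLY_IMPORTANT,sulfonamide,
sulfamethazine,sulphamethazine,HIGHLY_IMPORTANT,sulfonamide,synonym of sulfadimidine; kept as a separate entry as in the source catalogue
sulfachloropyridazine,sulphachloropyridazine,HIGHLY_IMPORTANT,sulfonamide,
sulfathiazole,sulphathiazole,HIGHLY_IMPORTANT,sulfonamide,
sulfamethoxypyridazine,sulphamethoxypyridazine,HIGHLY_IMPORTANT,sulfonamide,
sulfadiazine,sulphadiazine,HIGHLY_IMPORTANT,sulfonamide,
trimethoprim,,OTHER,diaminopyrimidine,
methenamine,hexamine,OTHER,other,
enramycin,,OTHER,polypeptide,
tiamulin,,OTHER,pleuromutilin,
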