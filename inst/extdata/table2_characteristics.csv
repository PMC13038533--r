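characteristic,level,n,printed_pct
Sex,Male,749,49.57
Sex,Female,549,36.33
Sex,Missing or unknown,213,14.10
Age,<=3,119,7.88
Age,4-18,95,6.29
Age,19-64,804,53.21
Age,>=65,132,8.74
Age,Missing or unknown,361,23.89
Indications,Iridocyclitis,122,8.07
Indications,Product used for unknown indication,115,7.61
Indications,Ophthalmological examination,36,2.38
Indications,Postoperative care,27,1.79
Indications,Fundoscopy,19,1.26
Indications,Mydriasis,16,1.06
Indications,Myopia,16,1.06
Indications,Strabismus,12,0.79
Indications,Toxicity to various agents,10,0.66
Indications,Cataract congenital,9,0.6
Indications,Endophthalmitis,9,0.6
Indications,Iritis,9,0.6
Indications,Preoperative care,9,0.6
Indications,Salivary hypersecretion,9,0.6
Indications,Uveitis,8,0.53
Indications,Others,142,9.39
Indications,Missing or unknown,943,62.40
Reporting countries,Canada,561,37.13
Reporting countries,France,307,20.32
Reporting countries,America,261,17.27
Reporting countries,United Kingdom,53,3.51
Reporting countries,Brazil,51,3.38
Reporting countries,Germany,44,2.91
Reporting countries,Italy,40,2.65
Reporting countries,Thailand,25,1.65
Reporting countries,Other countries,127,8.41
Reporting countries,Missing or unknown,42,2.78
Outcome,Other serious (important medical event),887,58.70
Outcome,Hospitalization - initial or prolonged,401,26.54
Outcome,Disability,82,5.43
Outcome,Death,42,2.78
Outcome,Life-threatening,24,1.59
Outcome,Missing or unknown,75,4.96
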