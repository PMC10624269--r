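quantity,Afghanistan,Morocco,Jordan
population,38928340,36910560,10203140
decedents,93373,76109,12283
nondecedents,77439,87346,11753
total_patients,172541,163898,22339
inpatient_days_referral_hospital,818291,586533,95847
outpatient_visits_referral_hospital,194418,264207,33539
inpatient_days_provincial_hospital,567408,302913,48218
outpatient_visits_provincial_hospital,164497,215410,24623
inpatient_days_district_hospital,502872,599917,86206
outpatient_visits_district_hospital,353407,473602,60769
inpatient_days_community_health_center,11633,14801,2229
outpatient_visits_community_health_center,375581,566372,68241
total_home_visits,5431684,5431684,997603
fte_doctor,722,682,100
fte_nurse,1443,1588,222
fte_social_worker,940,1051,147
fte_spiritual_counsellor,112,91,14
fte_psychologist_or_psychiatrist,77,49,8
fte_physical_therapist,27,17,3
fte_pharmacist,168,164,24
fte_community_health_worker,3018,4096,554
fte_clinical_support,12,10,2
fte_nonclinical_support,142,119,18
fte_per_100k_doctor,1.85,1.85,0.98
fte_per_100k_nurse,3.71,4.30,2.18
fte_per_100k_social_worker,2.42,2.85,1.44
fte_per_100k_spiritual_counsellor,0.29,0.25,0.14
fte_per_100k_psychologist_or_psychiatrist,0.20,0.13,0.08
fte_per_100k_physical_therapist,0.07,0.04,0.03
fte_per_100k_pharmacist,0.43,0.44,0.23
fte_per_100k_community_health_worker,7.75,11.10,5.43
fte_per_100k_clinical_support,0.03,0.03,0.02
fte_per_100k_nonclinical_support,0.36,0.32,0.18
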