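staff_category,level,hours_per_inpatient_day,hours_per_outpatient_visit,hours_per_home_visit,annual_fte_hours
doctor,referral_hospital,0.5,0.29999999999999999,0,1650
doctor,provincial_hospital,0.5,0.29999999999999999,0,1650
doctor,district_hospital,0.5,0.29999999999999999,0,1650
doctor,community_health_center,0.5,0.29999999999999999,0,1650
doctor,home,0,0,0,1650
nurse,referral_hospital,1.2,0.5,0,1650
nurse,provincial_hospital,1.2,0.5,0,1650
nurse,district_hospital,1.2,0.5,0,1650
nurse,community_health_center,1.2,0.5,0,1650
nurse,home,0,0,0,1650
social_worker,referral_hospital,0.29999999999999999,0.29999999999999999,0,1650
social_worker,provincial_hospital,0.29999999999999999,0.29999999999999999,0,1650
social_worker,district_hospital,0.29999999999999999,0.29999999999999999,0,1650
social_worker,community_health_center,0.29999999999999999,0.29999999999999999,0,1650
social_worker,home,0,0,0,1650
spiritual_counsellor,referral_hospital,0.10000000000000001,0.029999999999999999,0,1650
spiritual_counsellor,provincial_hospital,0.10000000000000001,0.029999999999999999,0,1650
spiritual_counsellor,district_hospital,0.10000000000000001,0.029999999999999999,0,1650
spiritual_counsellor,community_health_center,0.10000000000000001,0.029999999999999999,0,1650
spiritual_counsellor,home,0,0,0,1650
psychologist_or_psychiatrist,referral_hospital,0.059999999999999998,0.029999999999999999,0,1650
psychologist_or_psychiatrist,provincial_hospital,0.059999999999999998,0.029999999999999999,0,1650
psychologist_or_psychiatrist,district_hospital,0.059999999999999998,0.029999999999999999,0,1650
psychologist_or_psychiatrist,community_health_center,0.059999999999999998,0.029999999999999999,0,1650
psychologist_or_psychiatrist,home,0,0,0,1650
physical_therapist,referral_hospital,0.02,0.01,0,1650
physical_therapist,provincial_hospital,0.02,0.01,0,1650
physical_therapist,district_hospital,0.02,0.01,0,1650
physical_therapist,community_health_center,0.02,0.01,0,1650
physical_therapist,home,0,0,0,1650
pharmacist,referral_hospital,0.12,0.080000000000000002,0,1650
pharmacist,provincial_hospital,0.12,0.080000000000000002,0,1650
pharmacist,district_hospital,0.12,0.080000000000000002,0,1650
pharmacist,community_health_center,0.12,0.080000000000000002,0,1650
pharmacist,home,0,0,0,1650
community_health_worker,referral_hospital,0,0,0,1650
community_health_worker,provincial_hospital,0,0,0,1650
community_health_worker,district_hospital,0,0,0,1650
community_health_worker,community_health_center,0,0,0,1650
community_health_worker,home,0,0,1.25,1650
clinical_support,referral_hospital,0.01,0.0040000000000000001,0,1650
clinical_support,provincial_hospital,0.01,0.0040000000000000001,0,1650
clinical_support,district_hospital,0.01,0.0040000000000000001,0,1650
clinical_support,community_health_center,0.01,0.0040000000000000001,0,1650
clinical_support,home,0,0,0,1650
nonclinical_support,referral_hospital,0.10000000000000001,0.059999999999999998,0,1650
nonclinical_support,provincial_hospital,0.10000000000000001,0.059999999999999998,0,1650
nonclinical_support,district_hospital,0.10000000000000001,0.059999999999999998,0,1650
nonclinical_support,community_health_center,0.10000000000000001,0.059999999999999998,0,1650
nonclinical_support,home,0,0,0,1650
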