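code,name,decedent_need_fraction,nondecedent_need_fraction
MAL,malignant neoplasms,0.80000000000000004,0.29999999999999999
HIV,HIV/AIDS,0.90000000000000002,0.40000000000000002
TB,tuberculosis,0.75,0.20000000000000001
STROKE,cerebrovascular disease,0.59999999999999998,0.25
DEM,dementia,0.90000000000000002,0.59999999999999998
CIHD,chronic ischaemic heart disease,0.5,0.14999999999999999
NIHD,non-ischaemic heart disease,0.55000000000000004,0.14999999999999999
LUNG,chronic lung disease,0.69999999999999996,0.34999999999999998
LIVER,liver disease,0.59999999999999998,0.20000000000000001
RENAL,renal failure,0.59999999999999998,0.25
CNSI,inflammatory CNS disease,0.69999999999999996,0.29999999999999999
CNSD,degenerative CNS disease,0.80000000000000004,0.5
INJ,injuries,0.45000000000000001,0.10000000000000001
POIS,poisoning,0.40000000000000002,0
MSK,musculoskeletal disorders,0.34999999999999998,0.25
CONG,congenital malformations,0.65000000000000002,0.34999999999999998
PREM,prematurity and birth trauma,0.69999999999999996,0.20000000000000001
HEMF,haemorrhagic fevers,0.80000000000000004,0
PEM,protein-energy malnutrition,0.59999999999999998,0.29999999999999999
ATH,atherosclerosis,0.45000000000000001,0.10000000000000001
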