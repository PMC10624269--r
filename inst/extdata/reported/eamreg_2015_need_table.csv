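country,income_group,at_most_symptom_days_millions,at_least_symptom_days_millions,decedents_thousands,nondecedents_thousands,total_thousands
Afghanistan,low,40,13,95,71,166
Palestine,low,No data,No data,No data,No data,No data
Somalia,low,24,8,47,51,98
South Sudan,low,78,23,51,201,251
Egypt,lower-middle,142,43,254,174,428
Morocco,lower-middle,55,17,77,87,164
Pakistan,lower-middle,248,75,513,355,869
Syrian Arab Republic,lower-middle,26,8,51,72,123
Sudan,lower-middle,60,19,109,120,228
Tunisia,lower-middle,21,7,29,34,63
Yemen,lower-middle,26,9,56,49,109
Iran (Islamic Republic of),upper-middle,125,38,155,208,363
Iraq,upper-middle,33,11,71,72,143
Lebanon,upper-middle,11,3,14,17,31
Jordan,upper-middle,8,2,12,12,24
Libya,upper-middle,8,3,13,13,26
Bahrain,high,1,0,1,1,2
Kuwait,high,2,1,3,4,7
Oman,high,3,1,4,5,9
Qatar,high,1,0,1,2,3
Saudi Arabia,high,24,8,40,44,84
United Arab Emirates,high,3,1,6,5,11
Total,,940,289,1602,1596,3198
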