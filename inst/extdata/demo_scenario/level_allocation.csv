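income_group,level,inpatient_share,outpatient_share
high,community_health_center,0.01,0.34000000000000002
high,district_hospital,0.32000000000000001,0.33000000000000002
high,home,0,0
high,provincial_hospital,0.27000000000000002,0.14999999999999999
high,referral_hospital,0.40000000000000002,0.17999999999999999
low,community_health_center,0.01,0.34000000000000002
low,district_hospital,0.32000000000000001,0.33000000000000002
low,home,0,0
low,provincial_hospital,0.27000000000000002,0.14999999999999999
low,referral_hospital,0.40000000000000002,0.17999999999999999
lower-middle,community_health_center,0.01,0.34000000000000002
lower-middle,district_hospital,0.32000000000000001,0.33000000000000002
lower-middle,home,0,0
lower-middle,provincial_hospital,0.27000000000000002,0.14999999999999999
lower-middle,referral_hospital,0.40000000000000002,0.17999999999999999
upper-middle,community_health_center,0.01,0.34000000000000002
upper-middle,district_hospital,0.32000000000000001,0.33000000000000002
upper-middle,home,0,0
upper-middle,provincial_hospital,0.27000000000000002,0.14999999999999999
upper-middle,referral_hospital,0.40000000000000002,0.17999999999999999
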