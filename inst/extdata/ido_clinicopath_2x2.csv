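variable,comparison,stratum,n_negative_or_weak,n_positive_or_modstrong,printed_p
nodular_growth,ido_status,yes,11,10,0.050
nodular_growth,ido_status,no,17,4,0.050
mitoses_present,ido_status,yes,18,13,0.047
mitoses_present,ido_status,no,10,1,0.047
capsule_rupture,intensity_group,yes,0,4,0.014
capsule_rupture,intensity_group,no,6,2,0.014
overall_recurrence,ido_status,yes,16,20,0.014
overall_recurrence,ido_status,no,19,6,0.014
locoregional_recurrence,ido_status,yes,12,18,0.009
locoregional_recurrence,ido_status,no,24,9,0.009
distal_recurrence,ido_status,yes,16,19,0.040
distal_recurrence,ido_status,no,20,8,0.040
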