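# NVSS 2021 leading causes of mortality in the United States, deaths by gender.
# Source: National Vital Statistics System, 2021 final data (CDC). Counts as
# printed in the published leading-causes-by-gender table; 12 named causes
# (the union of the women's and men's top-10 lists) plus "other".
# Known issues, stored as printed and flagged by the loader rather than corrected:
#   - diabetes: women + men = 101,294 != total 103,294 (source-internal
#     inconsistency; proportions are computed from women+men, not the total).
# Variant numbers circulating for heart male deaths (384,866) and the accidents
# total (225,935) are transcription slips; this file carries the internally
# consistent table values (384,886 and 224,935).
# ICD-10 ranges follow the NVSS cause-of-death groupings.
cause,display_name,icd10_range,total,women,men
heart,Diseases of heart,I00-I09;I11;I13;I20-I51,695547,310661,384886
cancer,Cancer,C00-C97,605213,286543,318670
covid19,COVID-19,U07.1,416893,180283,236610
accidents,Accidents,V01-X59;Y85-Y86,224935,75333,149602
cerebrovascular,Cerebrovascular disease,I60-I69,162890,92038,70852
chronic_lower_respiratory,Chronic lower respiratory diseases,J40-J47,142342,74814,67528
alzheimer,Alzheimer disease,G30,119399,82424,36975
diabetes,Diabetes mellitus,E10-E14,103294,44666,56628
chronic_liver,Chronic liver disease,K70;K73-K74,56585,20878,35707
nephritis,Nephritis,N00-N07;N17-N19;N25-N27,54358,25769,28589
suicide,Suicide,U03;X60-X84;Y87.0,48183,9825,38358
hypertension,Essential hypertension,I10;I12;I15,42816,22730,20086
other,Other,,791776,400159,391617
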