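country,table,row,key,printed
Burkina Faso,2,Total population,cascade:total_population,20244080
Burkina Faso,2,Population at risk of noma,cascade:population_at_risk,14939063
Burkina Faso,2,Potential noma cases,cascade:potential_cases,95610
Burkina Faso,2,Potential noma cases receiving treatment,cascade:treated_cases,9561
Burkina Faso,3,Years of life lost,yll,55.2
Burkina Faso,4,Costs of treatment (population),direct_count:treatment,9561
Burkina Faso,4,Costs of treatment,direct_line:treatment,3298545
Burkina Faso,4,Costs of surgery (population),direct_count:surgery,5737
Burkina Faso,4,Costs of surgery,direct_line:surgery,2294800
Burkina Faso,4,Costs of accommodation (population),direct_count:accommodation,5737
Burkina Faso,4,Costs of accommodation,direct_line:accommodation,4388805
Burkina Faso,4,Costs of psychological management (population),direct_count:psychological,5737
Burkina Faso,4,Costs of psychological management,direct_line:psychological,372905
Burkina Faso,4,Costs of physiotherapy (population),direct_count:physiotherapy,5737
Burkina Faso,4,Costs of physiotherapy,direct_line:physiotherapy,1457198
Burkina Faso,4,Costs of assist. w. income-gen. activities (population),direct_count:income_assistance,5737
Burkina Faso,4,Costs of assist. w. income-gen. activities,direct_line:income_assistance,1406398
Burkina Faso,4,Costs of schooling/vocational training (population),direct_count:schooling,1950
Burkina Faso,4,Costs of schooling/vocational training,direct_line:schooling,341250
Burkina Faso,4,Costs of care abroad (population),direct_count:care_abroad,172
Burkina Faso,4,Costs of care abroad,direct_line:care_abroad,14620000
Burkina Faso,4,Direct costs total,direct_total,28179901
Burkina Faso,4,Costs of loss of production (population),indirect_count:lost_production,25870
Burkina Faso,4,Costs of loss of production,indirect_line:lost_production,19402500
Burkina Faso,4,Costs related to premature death (population),indirect_count:premature_death,86049
Burkina Faso,4,Costs related to premature death,indirect_line:premature_death,3562428600
Burkina Faso,4,Costs of inability to marry (population),indirect_count:inability_to_marry,13356
Burkina Faso,4,Costs of inability to marry,indirect_line:inability_to_marry,13365000
Burkina Faso,6,Direct costs total,direct_total,28179901
Burkina Faso,6,Costs of loss of production (population),indirect_count:lost_production,28581
Burkina Faso,6,Costs of loss of production,indirect_line:lost_production,19402500
Burkina Faso,6,Costs related to premature death (population),indirect_count:premature_death,95272
Burkina Faso,6,Costs related to premature death,indirect_line:premature_death,3562428600
Burkina Faso,6,Costs of inability to marry (population),indirect_count:inability_to_marry,14820
Burkina Faso,6,Costs of inability to marry,indirect_line:inability_to_marry,13365000
Niger,2,Total population,cascade:total_population,22442948
Niger,2,Population at risk of noma,cascade:population_at_risk,16540452
Niger,2,Potential noma cases,cascade:potential_cases,105858
Niger,2,Potential noma cases receiving treatment,cascade:treated_cases,10585
Niger,3,Years of life lost,yll,56
Niger,5,Costs of treatment (population),direct_count:treatment,10585
Niger,5,Costs of treatment,direct_line:treatment,3651825
Niger,5,Costs of surgery (population),direct_count:surgery,6372
Niger,5,Costs of surgery,direct_line:surgery,2548800
Niger,5,Costs of accommodation (population),direct_count:accommodation,6372
Niger,5,Costs of accommodation,direct_line:accommodation,4874580
Niger,5,Costs of psychological management (population),direct_count:psychological,6372
Niger,5,Costs of psychological management,direct_line:psychological,414180
Niger,5,Costs of physiotherapy (population),direct_count:physiotherapy,6372
Niger,5,Costs of physiotherapy,direct_line:physiotherapy,1618488
Niger,5,Costs of assist. w. income-gen. activities (population),direct_count:income_assistance,6372
Niger,5,Costs of assist. w. income-gen. activities,direct_line:income_assistance,1561140
Niger,5,Costs of schooling/vocational training (population),direct_count:schooling,2166
Niger,5,Costs of schooling/vocational training,direct_line:schooling,379050
Niger,5,Costs of care abroad (population),direct_count:care_abroad,185
Niger,5,Costs of care abroad,direct_line:care_abroad,15725000
Niger,5,Direct costs total,direct_total,30746063
Niger,5,Costs of loss of production (population),indirect_count:lost_production,28581
Niger,5,Costs of loss of production,indirect_line:lost_production,16291170
Niger,5,Costs related to premature death (population),indirect_count:premature_death,95272
Niger,5,Costs related to premature death,indirect_line:premature_death,3041082240
Niger,5,Costs of inability to marry (population),indirect_count:inability_to_marry,14820
Niger,5,Costs of inability to marry,indirect_line:inability_to_marry,14820000
Niger,6,Direct costs total,direct_total,30746063
Niger,6,Costs of loss of production (population),indirect_count:lost_production,28581
Niger,6,Costs of loss of production,indirect_line:lost_production,16291170
Niger,6,Costs related to premature death (population),indirect_count:premature_death,95272
Niger,6,Costs related to premature death,indirect_line:premature_death,3041082240
Niger,6,Costs of inability to marry (population),indirect_count:inability_to_marry,14820
Niger,6,Costs of inability to marry,indirect_line:inability_to_marry,14820000
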