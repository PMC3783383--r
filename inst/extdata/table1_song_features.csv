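species,collection_site,call_period_mean,call_period_se,call_duration_mean,call_duration_se,syllable_period_mean,syllable_period_se,syllable_duration_mean,syllable_duration_se,dominant_frequency_mean,dominant_frequency_se,relative_variance_mean,relative_variance_se,constancy_factor_mean,constancy_factor_se,n_individuals
Coiblemmus,Coimbatore,93.2,1.9,37.3,1.4,23.8,1.3,14.1,0.9,5.3,0.1,943.2,22.4,843.9,29.9,5
Gryllodes,Kuppam,130.1,6.4,46.8,1.6,16.3,0.7,20.6,0.6,5.9,0.1,59.7,8,5.6,0.9,6
Gryllus,Bangalore,345.5,11.9,166.9,4.3,36.8,1.3,20.6,0.6,5,0.1,57,9.4,16.9,2.6,6
Itaropsis_ssp1,Bangalore,11342.9,915.5,8343.1,983.2,99.7,2.8,40,1.1,6.6,0.2,5.5,1.4,7.5,1,6
Itaropsis_2,Kadari,1155.6,85,420.6,76.8,42.5,2.3,22.3,1.2,7.5,0.1,67.7,10.4,67.4,8.8,5
Itaropsis_3,Valparai,1504.4,122.2,296.5,16.8,54.9,1.3,26.4,0.8,6.5,0.1,125.1,18.7,122.5,17.2,7
Phonarellus_sp1,Kadari,467,14.6,312.1,22.2,35.8,1.8,12.8,0.9,6.9,0.1,124.7,25.6,35.5,5.1,6
Phonarellus,Bangalore,68.9,1,36.2,0.6,34.5,0.5,13.8,0.2,6.6,0.1,30.9,2.8,2.3,0.2,6
Platygryllus,Mudumalai,667.5,43.2,317.5,15.6,26.6,0.5,16.3,0.4,4.4,0.1,118.8,14.2,64.5,6.7,8
Plebiogryllus,Ullodu,217.8,7.7,122.7,6.4,31,0.6,17.7,0.4,6,0.1,224.8,36.7,57.4,13.3,7
Teleogryllus,Kadari,305.9,13.7,115.7,12.2,54.5,1.2,41.2,0.9,3.1,0.1,211.5,17,64.2,5.8,6
Turanogryllus,Mudumalai,863.2,29.7,600.6,34.2,8.9,0.2,5.6,0.3,6.2,0.1,167.2,16.5,136.2,18.7,8
Velarifictorus_sp1,Kuppam,9271,1445.2,1090.4,136.8,42.3,1.8,24,0.8,4.4,0.1,541.5,268.4,1692.7,330.9,5
Velarifictorus_sp2,Kadari,318.6,26.4,144.4,17.6,38.6,1.4,24.2,0.8,4.2,0.0,251.2,42.9,1474.4,101.3,4
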