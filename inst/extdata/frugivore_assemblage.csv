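species_id,common_name,functional_group,module,migratory,visits_MAR,visits_OJI,visits_COL,visits_total,feeding_rate,feeding_rate_se,seeds_dispersed,seeds_dispersed_se,seed_share_pct
Turdus_philomelos,song thrush,medium-sized bird,A,TRUE,9277,29322,45291,83890,4.37,0.77,723408,116725,82
Genetta_genetta,common genet,medium-sized mammal,A,FALSE,0,13,52,65,2.27,0.2,363,39,0.04
Turdus_merula,blackbird,medium-sized bird,B,FALSE,1119,3001,2677,6797,4.42,0.45,56005,6014,6.33
Erithacus_rubecula,robin,small-sized bird,B,FALSE,1998,5247,5368,12613,1.25,0.13,30783,3201,3.48
Vulpes_vulpes,red fox,medium-sized mammal,B,FALSE,312,296,802,1410,7.4,0.54,19935,2116,2.25
Oryctolagus_cuniculus,European rabbit,small-sized mammal,C,FALSE,1353,2240,27,3620,9.06,0.59,46981,4265,5.31
Turdus_iliacus,redwing,medium-sized bird,C,TRUE,65,229,76,370,5.18,0.4,3251,251,0.37
Meles_meles,European badger,medium-sized mammal,C,FALSE,37,9,6,52,19.83,2.21,2070,231,0.23
Curruca_melanocephala,Sardinian warbler,small-sized bird,C,FALSE,92,213,503,808,0.62,0,876,0,0.1
Cyanopica_cooki,Iberian magpie,medium-sized bird,C,FALSE,213,0,0,213,1.76,0,428,0,0.05
Turdus_torquatus,ring ouzel,medium-sized bird,C,TRUE,37,0,8,45,5.42,0.28,326,17,0.04
Sylvia_atricapilla,blackcap,small-sized bird,C,FALSE,52,53,0,105,1.33,0.33,271,101,0.03
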