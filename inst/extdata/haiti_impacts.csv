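year,neonatal_deaths,neonatal_deaths_low,neonatal_deaths_high,child_deaths,child_deaths_low,child_deaths_high,maternal_deaths,maternal_deaths_low,maternal_deaths_high,diarrhea_episodes,diarrhea_episodes_low,diarrhea_episodes_high,stunting_cases,stunting_cases_low,stunting_cases_high,anemia_cases,lbw_births
2016,577,101,1005,1249,254,2317,82,25,124,893000,529000,1226000,55000,32175,84425,28000,7600
2017,577,101,1005,1249,254,2317,82,25,124,893000,529000,1226000,55000,32175,84425,28000,7600
2018,577,101,1005,1249,254,2317,82,25,124,893000,529000,1226000,55000,32175,84425,28000,7600
2019,577,101,1005,1249,254,2317,82,25,124,893000,529000,1226000,55000,32175,84425,28000,7600
2020,577,101,1005,1249,254,2317,82,25,124,893000,529000,1226000,55000,32175,84425,28000,7600
2021,577,101,1005,1249,254,2317,82,25,124,893000,529000,1226000,55000,32175,84425,28000,7600
2022,577,101,1005,1249,254,2317,82,25,124,893000,529000,1226000,55000,32175,84425,28000,7600
2023,577,101,1005,1249,254,2317,82,25,124,893000,529000,1226000,55000,32175,84425,28000,7600
2024,577,101,1005,1249,254,2317,82,25,124,893000,529000,1226000,55000,32175,84425,28000,7600
2025,577,101,1005,1249,254,2317,82,25,124,893000,529000,1226000,55000,32175,84425,28000,7600
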