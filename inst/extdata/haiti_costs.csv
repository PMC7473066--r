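name,target,unit_cost_htg,annual_cost_htg_millions,basis
salt_iodization,population,2,0.5,iodization
micronutrient_calcium_pregnancy,mother,3200,746,direct_estimate
energy_protein_pregnancy,mother,3195,745,proportional
vitamin_a_child,child,250,39,direct_estimate
zinc_child,child,518,121,proportional
breastfeeding_promotion,mother,1830,253,proportional
complementary_feeding_education,mother,673,106,proportional
complementary_food_supplementation,mother,6390,1005,proportional
sam_management,child,165,4.3,sam_rule
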