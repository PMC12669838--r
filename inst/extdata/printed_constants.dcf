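fulmar_hill_slope: 2.74683
fulmar_hill_intercept: 4.52219
emperor_anchor_ph: 7.5 7.4 7.3 7.2
emperor_anchor_p50: 28 31 35 37
emperor_hill_n: 3.0
hb_conc_g_dl: 18.3
o2_capacity_ml_g: 1.34
solubility_ml_dl_mmhg: 0.003
blood_volume_ml_kg: 100
arterial_fraction: 0.33
venous_fraction: 0.67
mmhg_per_ata: 760
water_vapor_mmhg: 47
m_per_ata: 10
mb_desat_short_pct_min: 14.4
mb_desat_long_pct_min: 9.8
chest_rate_short: 3.1
chest_rate_long: 2.3
chest_store_ml_kg: 21.4
respiratory_air_ml_kg: 70
alldive_respiratory_dmr: 1.5
alldive_muscle_dmr: 3.6
table1_arterial_dmr_median_ph74: 0.4
table1_arterial_dmr_median_ph73: 0.5
table1_venous_dmr_median_ph74: 0.7
table1_venous_dmr_median_ph73: 0.9
lactate_split_mmol_l: 1.5
lactate_model_pco2_max_mmhg: 70
pco2_exclusion_mmhg: 93
anesthesia_pco2_max_mmhg: 70
arterial_baseline_sat: 0.90
venous_baseline_sat: 0.80
resting_ph: 7.5
adl_min: 5.6
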