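compartment,class,initial_ml_o2_kg,dmr_ml_o2_kg_min
arterial,short,7.3,0.4
venous,short,13.1,1.4
respiratory,short,12.2,1.6
muscle_chest,short,21.4,3.1
muscle_legs,short,3.0,0.5
arterial,long,8.0,0.4
venous,long,11.9,1.0
respiratory,long,12.2,0.9
muscle_chest,long,21.4,2.0
muscle_legs,long,3.0,0.3
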