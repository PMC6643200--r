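component,range_max,overall,mexican,central_american,cuban,dominican,puerto_rican,south_american
total_fruit,5,2.80,2.91,2.93,2.47,3.86,2.38,3.50
whole_fruit,5,3.05,3.95,3.39,2.69,4.63,2.50,3.90
total_veg,5,3.27,3.48,3.19,3.39,3.21,2.77,3.48
greens_beans,5,3.17,3.41,3.39,3.23,3.08,2.64,3.38
whole_grains,10,4.81,8.28,4.60,1.72,2.28,2.83,3.52
dairy,10,5.78,5.96,5.25,5.39,5.62,6.45,5.69
total_protein,5,4.92,4.94,4.96,4.97,4.98,4.87,4.92
seafood_plant_prot,5,3.95,4.18,4.33,4.01,4.30,3.41,3.93
fatty_acids,10,5.94,5.85,6.81,6.47,6.74,4.80,5.72
refined_grains,10,6.41,7.62,6.19,5.82,6.28,5.48,5.97
sodium,10,3.78,4.84,3.41,2.25,3.25,3.89,2.79
empty_calories,20,15.93,15.72,16.25,16.79,17.70,14.44,16.53
total,100,63.82,71.14,64.69,59.20,65.92,56.45,63.35
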