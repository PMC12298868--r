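trait,mean,sd,cv_percent,gdi
growth_period,148.47,6.571,4.43,0.728
tassel_branch_number,7.78,4.314,55.45,1.204
plant_height,203.36,28.659,14.09,1.556
ear_position_height,76.22,19.758,25.92,1.673
ear_stem_length,8.95,3.832,42.82,0.812
ear_length,16.57,2.935,17.71,1.005
ear_thickness,4.58,0.515,11.24,1.566
ear_row_number,14.8,2.533,17.11,1.41
row_grain_number,27.05,5.989,22.14,0.881
ear_type,2.12,0.832,39.25,1.205
grain_length,10.24,1.29,12.60,1.519
grain_width,8.63,0.938,10.87,1.283
grain_thickness,4.94,0.632,12.79,0.827
grain_type,1.84,0.733,39.84,1.052
hundred_grain_weight,28.6,5.795,20.26,1.597
total_grain_per_ear,99.19,40.249,40.58,1.441
dry_weight_per_ear,125.49,50.424,40.18,1.4
seed_emergence_rate,0.79,0.074,9.37,1.059
plot_yield,1547,875.683,56.61,1.178
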