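pin_diameter_mm,load_N,stroke_mm,rotation_deg,weeks,stress_reported_mpa,p_over_e_reported,cs_reported
5,80,28,30,3,4,0.007,0.087
5,216,28,30,3,11,0.020,0.087
4,252,28,30,3,20,0.036,0.087
3,212,28,30,3,30,0.054,0.087
3,283,28,30,3,40,0.071,0.087
2,252,28,30,3,80,0.143,0.087
5,216,28,0,2,11,0.020,0
5,216,10,10,5,11,0.020,0.012
5,216,12,15,2,11,0.020,0.022
5,216,26,45,2,11,0.020,0.18
5,80,10,10,2,4,0.007,0.012
2,252,10,10,4,80,0.143,0.012
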