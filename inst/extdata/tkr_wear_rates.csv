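activity,predicted_mm3_per_mc,experimental_mm3_per_mc,experimental_ci95
walking,4.5,5.8,1.4
deep_squat,3.7,3.5,0.8
stairs_ascent,5.6,7.1,2.0
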