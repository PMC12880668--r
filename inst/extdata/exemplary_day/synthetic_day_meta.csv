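patient_id,window_start,basal,hr_rest,start_min
P01,2024-03-01,0.013194444444444444,60,0
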