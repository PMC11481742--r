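input_mode,filter_threshold,n_herbs_mean,n_herbs_sd,precision,recall,f1,iou
symptom,0.1,3.77,1.34,0.49,0.20,0.28,0.17
symptom,0.2,6.07,1.48,0.42,0.27,0.33,0.20
symptom,0.3,10.12,1.77,0.34,0.37,0.36,0.22
symptom,0.4,20.52,2.63,0.25,0.55,0.35,0.21
symptom_plus_scheme,0.1,5.44,2.39,0.65,0.38,0.48,0.33
symptom_plus_scheme,0.2,7.04,2.60,0.59,0.44,0.50,0.34
symptom_plus_scheme,0.3,9.72,2.80,0.50,0.51,0.50,0.34
symptom_plus_scheme,0.4,16.00,3.03,0.37,0.61,0.46,0.30
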