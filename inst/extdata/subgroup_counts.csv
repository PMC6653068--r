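characteristic,n_1A_with,n_1A_total,n_1B_with,n_1B_total
female,55,69,28,32
male,14,69,4,32
caucasian,39,69,12,32
asian,28,69,18,32
ethnicity_other,2,69,2,32
age_dx_lt18,5,69,6,32
age_dx_18_45,49,69,21,32
age_dx_ge45,15,69,5,32
duration_lt10,24,69,12,32
duration_ge10,45,69,20,32
neurological,2,69,4,32
musculoskeletal,5,69,12,32
renal,3,69,7,32
mucocutaneous,10,69,21,32
serositis,0,69,2,32
immunological,13,69,28,32
hematological,3,69,4,32
sfi_flare,45,69,28,32
sdi_ge1,34,69,23,32
sledai_gt4,44,69,29,32
ams_q1,7,69,19,32
prednisolone,51,69,32,32
pred_gt7p5,39,69,30,32
hydroxychloroquine,66,69,31,32
immunosuppressants,46,69,32,32
biologics,1,69,6,32
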