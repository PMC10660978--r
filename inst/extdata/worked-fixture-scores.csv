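patient_id,total,excluded,note
FIX-A,0,FALSE,empty record
FIX-B,3,FALSE,8 GP visits in 1 year
FIX-C,7.5,FALSE,5 antibiotic prescriptions x 1.5
FIX-D,6.5,FALSE,2 pneumonia x 2.5 + sinusitis 1.5
FIX-E,4.5,TRUE,HIV code excludes; 3 prescriptions x 1.5
FIX-F,3,FALSE,censored at lymphoma 2019-05-01; 2 prescriptions count
FIX-G,22.5,FALSE,9 + 6 + 2 + 1.5 + 1 + 3
FIX-H,6,FALSE,recorded low IgM 5 + URI 1
FIX-I,0,FALSE,all events outside lookback windows
FIX-J,3,FALSE,exactly 6 GP visits meets threshold
FIX-K,0,TRUE,age 10 outside 12-70
FIX-L,3,FALSE,IBD once 1.5 + splenomegaly 1.5
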