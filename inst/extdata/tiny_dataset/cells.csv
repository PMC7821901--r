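cell_id,cell_class,reliability_p,response_amp,sustained,location
cell_01,stop_excited,0.8,10,FALSE,lateral
cell_02,stop_inhibited,0.8,10,FALSE,medial
cell_03,grooming_excited,0.8,10,FALSE,lateral
cell_04,uncorrelated,0.8,10,FALSE,medial
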