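type,onset_s,offset_s
grooming,12.5,18.0
grooming,33.25,40.5
grooming,51.0,58.75
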