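event,onset_s,onset_frame,offset_s,provenance
grooming,0.5,10,5.854508556089498,ground_truth
start,5.9,118,9.45,ground_truth
stop,9.45,189,14.9,ground_truth
long_stop,9.45,189,14.9,ground_truth
grooming,9.929301986986268,199,14.80816437375961,ground_truth
start,14.9,298,18.6,ground_truth
stop,18.6,372,23.45,ground_truth
long_stop,18.6,372,23.45,ground_truth
grooming,19.070047520694455,381,23.387685534340008,ground_truth
start,23.45,469,25.3,ground_truth
stop,25.3,506,30.15,ground_truth
long_stop,25.3,506,30.15,ground_truth
grooming,25.754016381949796,515,30.099552952777806,ground_truth
start,30.15,603,32.3,ground_truth
stop,32.3,646,37.45,ground_truth
long_stop,32.3,646,37.45,ground_truth
grooming,32.756830139139936,655,37.405185444166754,ground_truth
start,37.45,749,39.15,ground_truth
stop,39.15,783,46.2,ground_truth
long_stop,39.15,783,46.2,ground_truth
grooming,39.61334209831232,792,46.13897811529879,ground_truth
start,46.2,924,48.4,ground_truth
stop,48.4,968,56.05,ground_truth
long_stop,48.4,968,56.05,ground_truth
grooming,48.851475222857374,977,55.95981860023069,ground_truth
start,56.05,1121,NA,ground_truth
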