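state,start_s,end_s
stationary,0,0.5
grooming,0.5,5.854508556089498
forward,5.854508556089498,9.429301986986268
stationary,9.429301986986268,9.929301986986268
grooming,9.929301986986268,14.80816437375961
forward,14.80816437375961,18.570047520694455
stationary,18.570047520694455,19.070047520694455
grooming,19.070047520694455,23.387685534340008
forward,23.387685534340008,25.254016381949796
stationary,25.254016381949796,25.754016381949796
grooming,25.754016381949796,30.099552952777806
forward,30.099552952777806,32.256830139139936
stationary,32.256830139139936,32.756830139139936
grooming,32.756830139139936,37.405185444166754
forward,37.405185444166754,39.11334209831232
stationary,39.11334209831232,39.61334209831232
grooming,39.61334209831232,46.13897811529879
forward,46.13897811529879,48.351475222857374
stationary,48.351475222857374,48.851475222857374
grooming,48.851475222857374,55.95981860023069
forward,55.95981860023069,60
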