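biomarker,low,high
apd90,180,440
apd50,110,350
rmp,-95,-80
vpeak,10,60
dvdt_max,100,1000
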