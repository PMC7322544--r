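approach,kind,assay,channel,transform,biomarker,rank
PX,potency,PX,IKr,pic50,,
PX,potency,PX,IKr,hill,,
PX,potency,HTS,ICaL,pic50,,
PX,potency,PX,INa,pic50,,
PX,simulated,,,,dvdt_max,3
PX,simulated,,,,rmp,4
PX,simulated,,,,vpeak,5
PX,simulated,,,,apd50,3
HTS,potency,HTS,IKr,pic50,,
HTS,potency,HTS,INa,pic50,,
HTS,potency,HTS,ICaL,pic50,,
HTS,simulated,,,,rmp,5
HTS,simulated,,,,ctd50,2
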