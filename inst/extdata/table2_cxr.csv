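category,ALVEOLAR_LUNG,ALVEOLAR_CARDIAC,VENT_ALVEOLAR,PERFUSION,METABOLIC
ALVEOLAR_LUNG,53,5,10,0,3
ALVEOLAR_CARDIAC,8,50,3,3,5
VENT_ALVEOLAR,1,0,4,0,0
PERFUSION,1,0,1,3,19
METABOLIC,0,0,0,0,5
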