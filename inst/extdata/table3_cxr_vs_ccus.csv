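category,ALVEOLAR_LUNG,ALVEOLAR_CARDIAC,VENT_ALVEOLAR,PERFUSION,METABOLIC
ALVEOLAR_LUNG,53,8,8,0,2
ALVEOLAR_CARDIAC,12,50,5,2,0
VENT_ALVEOLAR,1,0,4,0,0
PERFUSION,2,2,2,2,16
METABOLIC,1,0,0,0,4
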