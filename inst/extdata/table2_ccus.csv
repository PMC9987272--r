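category,ALVEOLAR_LUNG,ALVEOLAR_CARDIAC,VENT_ALVEOLAR,PERFUSION,METABOLIC
ALVEOLAR_LUNG,54,3,3,0,9
ALVEOLAR_CARDIAC,5,52,0,0,3
VENT_ALVEOLAR,2,0,15,2,0
PERFUSION,0,0,0,4,0
METABOLIC,2,0,0,0,20
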