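# Proteins with prior plasma-membrane localization whose FFE profiles run
# anodic (samples 13-19), overlapping tonoplast markers.
gene	annotated_compartment
NHX7	PM
NCL	PM
AMT1-1	PM
TauE	PM
ABCG40	PM
ABCC4	PM
ENT1	PM
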