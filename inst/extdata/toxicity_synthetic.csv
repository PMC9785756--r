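compound_id,trophic_level,ec50_mg_L,source
SMX,algae,0.612,experimental
SMZ,algae,3.235,experimental
ERY,algae,0.056,experimental
SMX,daphnia,25.2,literature
SMZ,daphnia,202.3,literature
ERY,daphnia,9.1,literature
SMX,fish,562,literature
SMZ,fish,100.5,literature
ERY,fish,349,literature
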