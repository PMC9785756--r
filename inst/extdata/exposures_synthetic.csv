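compound_id,environment,mec,mec_unit
SMX,surface_water,1.9,ug/L
SMZ,surface_water,0.63,ug/L
ERY,surface_water,1.7,ug/L
SMX,wastewater,6.8,ug/L
SMZ,wastewater,18.5,ug/L
ERY,wastewater,3.8,ug/L
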