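flow,unit,category,factor,note
electricity,kWh,GWP100,0.4405,grid factor implied by 0.79 kWh/kg COD <-> 348 kg CO2eq/tonne conversion
natural_gas,MJ,GWP100,0.0692,combustion 56.6 g CO2/MJ plus synthetic upstream share
natural_gas_avoided,MJ,GWP100,0.015,avoided-supply credit per MJ of biogas heat; scaled to an expected credit band of roughly -150 to -205 kg CO2eq per tonne COD removed
ch4_fugitive,kg,GWP100,28,methane GWP100 (configurable)
peg_encapsulant,kg,GWP100,3.0,synthetic placeholder for PEG production
concrete,m3,GWP100,320,synthetic placeholder ready-mix concrete
rockwool,m3,GWP100,160,synthetic placeholder mineral wool
carbon_steel,kg,GWP100,1.9,synthetic placeholder steel sheet
stainless_steel,kg,GWP100,4.6,synthetic placeholder stainless
hdpe,kg,GWP100,2.0,synthetic placeholder HDPE granulate + extrusion
membrane_contactor,m2,GWP100,16,synthetic placeholder polymeric membrane module
equipment_mass,kg,GWP100,3.5,synthetic placeholder generic machinery per kg
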