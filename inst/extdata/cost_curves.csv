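item,base_cost_usd2021,base_size,unit,exponent,install_factor,lifetime_yr,note
concrete,165,1,m3,1,2.0,30,synthetic placeholder unit price of structural concrete in place
rockwool,220,1,m3,1,1.5,30,synthetic placeholder insulation board
carbon_steel,1.6,1,kg,1,1.8,30,synthetic placeholder exterior facing sheet
stainless_steel,4.8,1,kg,1,1.8,15,synthetic placeholder fabricated stainless (separators and gas piping)
hdpe,2.1,1,kg,1,1.6,30,synthetic placeholder HDPE pipe
peg_encapsulant,9.0,1,kg,1,1.1,1,synthetic placeholder PEG hydrogel bead (lifetime set per scenario)
membrane_contactor,210,1,m2,1,1.5,10,synthetic placeholder hollow-fiber membrane area
water_pump,6200,2,kW,0.6,1.8,15,synthetic placeholder centrifugal pump skid
vacuum_pump,13000,2,kW,0.6,1.8,15,synthetic placeholder liquid-ring vacuum pump
heat_exchanger,16000,50,kW,0.7,1.8,15,synthetic placeholder plate heat exchanger
gas_holder,21000,100,m3,0.6,1.5,15,synthetic placeholder double-membrane biogas holder
iron_sponge_scrubber,8500,100,Nm3/d,0.6,1.5,15,synthetic placeholder H2S scrubber vessel
control_system,18000,1,unit,1,1.2,15,synthetic placeholder instrumentation and control
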