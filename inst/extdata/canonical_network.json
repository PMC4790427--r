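{"pools":[{"name":"Glc_p","compartment":"input","n_carbons":6,"is_input":true,"hot_positions":[1,6]},{"name":"Glc_b","compartment":"shared","n_carbons":6,"concentration":1.2,"is_input":false,"hot_positions":[]},{"name":"Lac","compartment":"shared","n_carbons":3,"concentration":1,"is_input":false,"hot_positions":[]},{"name":"Pyr_n","compartment":"neuronal","n_carbons":3,"concentration":0.15,"is_input":false,"hot_positions":[]},{"name":"Pyr_g","compartment":"glial","n_carbons":3,"concentration":0.15,"is_input":false,"hot_positions":[]},{"name":"AcCoA_n","compartment":"neuronal","n_carbons":2,"concentration":0.1,"is_input":false,"hot_positions":[]},{"name":"AcCoA_g","compartment":"glial","n_carbons":2,"concentration":0.1,"is_input":false,"hot_positions":[]},{"name":"OG_n","compartment":"neuronal","n_carbons":5,"concentration":0.2,"is_input":false,"hot_positions":[]},{"name":"OG_g","compartment":"glial","n_carbons":5,"concentration":0.1,"is_input":false,"hot_positions":[]},{"name":"Glu_n","compartment":"neuronal","n_carbons":5,"concentration":7.56,"is_input":false,"hot_positions":[]},{"name":"Glu_g","compartment":"glial","n_carbons":5,"concentration":0.84,"is_input":false,"hot_positions":[]},{"name":"Gln","compartment":"glial","n_carbons":5,"concentration":4.3,"is_input":false,"hot_positions":[]},{"name":"OAA_n","compartment":"neuronal","n_carbons":4,"concentration":0.1,"is_input":false,"hot_positions":[]},{"name":"OAA_g","compartment":"glial","n_carbons":4,"concentration":0.1,"is_input":false,"hot_positions":[]},{"name":"Asp_n","compartment":"neuronal","n_carbons":4,"concentration":1.5,"is_input":false,"hot_positions":[]},{"name":"Asp_g","compartment":"glial","n_carbons":4,"concentration":1,"is_input":false,"hot_positions":[]},{"name":"CO2","compartment":"shared","n_carbons":1,"concentration":1,"is_input":false,"hot_positions":[]}],"reactions":[{"name":"glc_transport","flux":"CMRglc","substrates":{"Glc_p":1},"products":{"Glc_b":[{"weight":1,"map":["Glc_p.1","Glc_p.2","Glc_p.3","Glc_p.4","Glc_p.5","Glc_p.6"]}]}},{"name":"glycolysis_n","flux":"Vgly_n","substrates":{"Glc_b":0.5},"products":{"Pyr_n":[{"weight":0.5,"map":["Glc_b.3","Glc_b.2","Glc_b.1"]},{"weight":0.5,"map":["Glc_b.4","Glc_b.5","Glc_b.6"]}]}},{"name":"glycolysis_g","flux":"Vgly_g","substrates":{"Glc_b":0.5},"products":{"Pyr_g":[{"weight":0.5,"map":["Glc_b.3","Glc_b.2","Glc_b.1"]},{"weight":0.5,"map":["Glc_b.4","Glc_b.5","Glc_b.6"]}]}},{"name":"ldh_n_fwd","flux":"Vex_lac","substrates":{"Pyr_n":1},"products":{"Lac":[{"weight":1,"map":["Pyr_n.1","Pyr_n.2","Pyr_n.3"]}]}},{"name":"ldh_n_rev","flux":"Vex_lac","substrates":{"Lac":1},"products":{"Pyr_n":[{"weight":1,"map":["Lac.1","Lac.2","Lac.3"]}]}},{"name":"ldh_g_fwd","flux":"Vex_lac","substrates":{"Pyr_g":1},"products":{"Lac":[{"weight":1,"map":["Pyr_g.1","Pyr_g.2","Pyr_g.3"]}]}},{"name":"ldh_g_rev","flux":"Vex_lac","substrates":{"Lac":1},"products":{"Pyr_g":[{"weight":1,"map":["Lac.1","Lac.2","Lac.3"]}]}},{"name":"lac_inflow","flux":"Vin","substrates":[],"products":{"Lac":[{"weight":1,"map":["*","*","*"]}]}},{"name":"lac_efflux","flux":"Vout","substrates":{"Lac":1},"products":[]},{"name":"pdh_n","flux":"Vpdh_n","substrates":{"Pyr_n":1},"products":{"AcCoA_n":[{"weight":1,"map":["Pyr_n.2","Pyr_n.3"]}],"CO2":[{"weight":1,"map":["Pyr_n.1"]}]}},{"name":"pdh_g","flux":"Vpdh_g","substrates":{"Pyr_g":1},"products":{"AcCoA_g":[{"weight":1,"map":["Pyr_g.2","Pyr_g.3"]}],"CO2":[{"weight":1,"map":["Pyr_g.1"]}]}},{"name":"acdil_in","flux":"Vdil","substrates":[],"products":{"AcCoA_g":[{"weight":1,"map":["*","*"]}]}},{"name":"acdil_out","flux":"Vdil","substrates":{"AcCoA_g":1},"products":[]},{"name":"cs_n","flux":"VTCA_n","substrates":{"OAA_n":1,"AcCoA_n":1},"products":{"OG_n":[{"weight":1,"map":["OAA_n.4","OAA_n.3","OAA_n.2","AcCoA_n.2","AcCoA_n.1"]}],"CO2":[{"weight":1,"map":["OAA_n.1"]}]}},{"name":"cs_g","flux":"VTCA_g","substrates":{"OAA_g":1,"AcCoA_g":1},"products":{"OG_g":[{"weight":1,"map":["OAA_g.4","OAA_g.3","OAA_g.2","AcCoA_g.2","AcCoA_g.1"]}],"CO2":[{"weight":1,"map":["OAA_g.1"]}]}},{"name":"ogdh_n","flux":"VTCA_n","substrates":{"OG_n":1},"products":{"OAA_n":[{"weight":0.5,"map":["OG_n.2","OG_n.3","OG_n.4","OG_n.5"]},{"weight":0.5,"map":["OG_n.5","OG_n.4","OG_n.3","OG_n.2"]}],"CO2":[{"weight":1,"map":["OG_n.1"]}]}},{"name":"ogdh_g","flux":"Vogdh_g","substrates":{"OG_g":1},"products":{"OAA_g":[{"weight":0.5,"map":["OG_g.2","OG_g.3","OG_g.4","OG_g.5"]},{"weight":0.5,"map":["OG_g.5","OG_g.4","OG_g.3","OG_g.2"]}],"CO2":[{"weight":1,"map":["OG_g.1"]}]}},{"name":"pc","flux":"Vpc","substrates":{"Pyr_g":1,"CO2":1},"products":{"OAA_g":[{"weight":1,"map":["Pyr_g.1","Pyr_g.2","Pyr_g.3","CO2.1"]}]}},{"name":"vx_og_glu_n_f","flux":"Vx","substrates":{"OG_n":1},"products":{"Glu_n":[{"weight":1,"map":["OG_n.1","OG_n.2","OG_n.3","OG_n.4","OG_n.5"]}]}},{"name":"vx_og_glu_n_r","flux":"Vx","substrates":{"Glu_n":1},"products":{"OG_n":[{"weight":1,"map":["Glu_n.1","Glu_n.2","Glu_n.3","Glu_n.4","Glu_n.5"]}]}},{"name":"vx_oaa_asp_n_f","flux":"Vx","substrates":{"OAA_n":1},"products":{"Asp_n":[{"weight":1,"map":["OAA_n.1","OAA_n.2","OAA_n.3","OAA_n.4"]}]}},{"name":"vx_oaa_asp_n_r","flux":"Vx","substrates":{"Asp_n":1},"products":{"OAA_n":[{"weight":1,"map":["Asp_n.1","Asp_n.2","Asp_n.3","Asp_n.4"]}]}},{"name":"vx_og_glu_g_f","flux":"Vglu_g_in","substrates":{"OG_g":1},"products":{"Glu_g":[{"weight":1,"map":["OG_g.1","OG_g.2","OG_g.3","OG_g.4","OG_g.5"]}]}},{"name":"vx_og_glu_g_r","flux":"Vx","substrates":{"Glu_g":1},"products":{"OG_g":[{"weight":1,"map":["Glu_g.1","Glu_g.2","Glu_g.3","Glu_g.4","Glu_g.5"]}]}},{"name":"vx_oaa_asp_g_f","flux":"Vx","substrates":{"OAA_g":1},"products":{"Asp_g":[{"weight":1,"map":["OAA_g.1","OAA_g.2","OAA_g.3","OAA_g.4"]}]}},{"name":"vx_oaa_asp_g_r","flux":"Vx","substrates":{"Asp_g":1},"products":{"OAA_g":[{"weight":1,"map":["Asp_g.1","Asp_g.2","Asp_g.3","Asp_g.4"]}]}},{"name":"gln_synthetase","flux":"Vsyn","substrates":{"Glu_g":1},"products":{"Gln":[{"weight":1,"map":["Glu_g.1","Glu_g.2","Glu_g.3","Glu_g.4","Glu_g.5"]}]}},{"name":"glu_release","flux":"Vnt","substrates":{"Glu_n":1},"products":{"Glu_g":[{"weight":1,"map":["Glu_n.1","Glu_n.2","Glu_n.3","Glu_n.4","Glu_n.5"]}]}},{"name":"glnase_n","flux":"Vnt","substrates":{"Gln":1},"products":{"Glu_n":[{"weight":1,"map":["Gln.1","Gln.2","Gln.3","Gln.4","Gln.5"]}]}},{"name":"gln_efflux","flux":"Vefflux","substrates":{"Gln":1},"products":[]},{"name":"co2_efflux","flux":"Vco2_out","substrates":{"CO2":1},"products":[]}],"measured_pools":["Glu_n","Glu_g","Gln"],"observables":{"glu":["Glu_n","Glu_g"],"gln":["Gln"]},"constants":{"Vex_lac":0.5}}
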