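isotope,compartment,q_g,ea_ev,g_o2
U238,seawater,1.59e-05,5.17e7,0.5
U235,seawater,1.15e-07,4.64e7,0.5
Th232,seawater,2.4e-10,4.26e7,0.5
K40,seawater,2.26e-04,1.3e6,0.2
U238,nodule,8.44e-03,5.17e7,0.5
U235,nodule,6.2e-05,4.64e7,0.5
Th232,nodule,3.4e-02,4.26e7,0.5
K40,nodule,1.6e-03,1.3e6,0.2
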