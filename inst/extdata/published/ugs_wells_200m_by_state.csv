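state,wells,wells_with_rhu,uncapped_rhus,par_ppa,par_abode_capped,par_abode_uncapped,wilcoxon_z
CA,346,41,400,1216,895,939,3.11
MI,2394,668,2027,4740,4283,5158,6.64
NY,972,362,996,2495,2393,2691,3.81
OH,3318,1680,12014,27593,29184,31273,1.11
PA,1332,577,3709,4996,7421,9336,-5.99
WV,1472,488,1791,2012,3093,3853,0.79
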