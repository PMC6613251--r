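column,printed_total
wells,9834
wells_with_rhu,3816
uncapped_rhus,20937
par_ppa,43052
par_abode_capped,48126
par_abode_uncapped,53250
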