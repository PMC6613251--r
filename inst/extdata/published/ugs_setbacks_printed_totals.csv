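column,printed_total
facilities_with_conflict,69
wells_with_conflict,444
rhus_within_setback,905
par_ppa,2861
par_abode,2171
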