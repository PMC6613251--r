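printed_rank,storage_field,state,rhus,par_abode_capped,par_ppa,printed_difference,printed_ppa_rank
1,Playa Del Rey,CA,150,341,375,-34,1
2,Zane Storage,OH,142,318,259,59,8
4,Medina,OH,88,257,87,170,109
5,Oakford,PA,146,255,127,128,43
6,Murrysville,PA,98,244,201,43,10
9,Stark-Summit,OH,95,221,162,59,20
10,Stark-Summit,OH,77,221,203,18,9
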