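comparison,year,author,design,n_exp,n_ctl,n_total,followup_lo,followup_hi
rfa_tace_vs_rfa,2013,Peng ZW,RCT,94,95,189,7,62
rfa_tace_vs_rfa,2012,Kim JW,RS,83,231,314,0,108
rfa_tace_vs_rfa,2012,Peng ZW,RCT,69,70,139,0,103
rfa_tace_vs_rfa,2010,Morimoto M,RCT,19,18,37,12,46
rfa_tace_vs_rfa,2010,Peng ZW,CCS,120,120,240,0,64
rfa_tace_vs_rfa,2009,Shibata T,RCT,46,43,89,9,68
rfa_tace_vs_rfa,2005,Shen SQ,CCS,18,16,34,5,38
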