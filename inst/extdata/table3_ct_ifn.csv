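comparison,year,author,design,n_exp,n_ctl,n_total,followup_lo,followup_hi
ct_ifn_vs_ct,2012,Chen LT,RCT,133,135,268,0,66.9
ct_ifn_vs_ct,2011,Hagihara H,CCT,37,145,182,0,120
ct_ifn_vs_ct,2007,Lo C M,RCT,40,40,80,0,160
ct_ifn_vs_ct,2007,Jeong SC,CCT,42,42,84,0,144
ct_ifn_vs_ct,2007,Jeong SC,CCT,16,16,32,0,45
ct_ifn_vs_ct,2007,Kudo M,CCT,43,84,127,0,100
ct_ifn_vs_ct,2006,Sun HC,RCT,118,118,236,0,68
ct_ifn_vs_ct,2003,Shiratori Y,RCT,49,25,74,0,108
ct_ifn_vs_ct,2002,Miyaguchi S,CCT,22,24,46,0,45
ct_ifn_vs_ct,2001,Suou T,CCT,18,22,40,0,110
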