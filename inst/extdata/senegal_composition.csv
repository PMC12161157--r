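variable,level,n,printed_pct
education,none,118081,62
education,primary,37849,20
education,secondary,31322,16
education,higher,2795,1
education,other,3,0
education,missing,3,0
dob_complete,complete,67841,36
dob_complete,imputed,122212,64
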