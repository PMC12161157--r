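birth_cohort,n_women,n_daughters,printed_pct
1960-1969,6431,0,3
1970-1979,20022,0,11
1980-1989,34192,0,18
1990-1999,33477,421,18
2000-2009,12930,37265,26
2010-2019,0,41174,22
after2020,0,3269,2
missing,872,0,0
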