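survey,module,n_obs,n_fgm,printed_pct
2005,women,14599,5274,36
2005,both,14599,5274,36
2010-2011,women,15688,5689,36
2010-2011,daughters,10499,1971,19
2010-2011,both,26187,7660,29
2012-2013,daughters,2805,622,22
2012-2013,both,2805,622,22
2014,women,8488,2858,34
2014,daughters,7879,1454,18
2014,both,16367,4312,26
2015,women,8851,3155,36
2015,daughters,8200,1787,22
2015,both,17051,4942,29
2016,women,8865,3128,35
2016,daughters,7916,1618,20
2016,both,16781,4746,28
2017,women,16787,5719,34
2017,daughters,15028,3065,20
2017,both,31815,8784,28
2018,women,9414,3094,33
2018,daughters,8379,1759,21
2018,both,17793,4853,27
2019,women,8649,3303,38
2019,daughters,7828,1878,24
2019,both,16477,5181,31
2023,women,16583,4950,30
2023,daughters,13595,2506,18
2023,both,30178,7456,25
total,women,107924,37170,34
total,daughters,82129,16660,20
total,both,190053,53830,28
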