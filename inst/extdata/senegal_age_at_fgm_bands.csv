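module,band,n,printed_pct
women,<1,6847,18
women,1-5,22852,61
women,6-10,4205,11
women,11-15,817,2
women,>15,93,0
women,missing,2356,6
daughters,<1,7858,47
daughters,1-5,7993,48
daughters,6-10,556,3
daughters,11-15,14,0
daughters,>15,0,0
daughters,missing,239,1
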