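# 6X flattened 6 MV energy spectrum (parametric preset)
# columns: energy_lo,energy_hi,fluence (MeV, relative)
energy_lo,energy_hi,fluence
0.25000,0.39375,0.01442347
0.39375,0.53750,0.03689749
0.53750,0.68125,0.05158880
0.68125,0.82500,0.06044951
0.82500,0.96875,0.06500013
0.96875,1.11250,0.06641872
1.11250,1.25625,0.06561244
1.25625,1.40000,0.06327474
1.40000,1.54375,0.05993119
1.54375,1.68750,0.05597588
1.68750,1.83125,0.05170048
1.83125,1.97500,0.04731728
1.97500,2.11875,0.04297738
2.11875,2.26250,0.03878510
2.26250,2.40625,0.03480929
2.40625,2.55000,0.03109213
2.55000,2.69375,0.02765609
2.69375,2.83750,0.02450926
2.83750,2.98125,0.02164944
2.98125,3.12500,0.01906735
3.12500,3.26875,0.01674899
3.26875,3.41250,0.01467745
3.41250,3.55625,0.01283426
3.55625,3.70000,0.01120034
3.70000,3.84375,0.00975671
3.84375,3.98750,0.00848498
3.98750,4.13125,0.00736764
4.13125,4.27500,0.00638833
4.27500,4.41875,0.00553185
4.41875,4.56250,0.00478429
4.56250,4.70625,0.00413300
4.70625,4.85000,0.00356653
4.85000,4.99375,0.00307459
4.99375,5.13750,0.00264800
5.13750,5.28125,0.00227856
5.28125,5.42500,0.00195901
5.42500,5.56875,0.00168295
5.56875,5.71250,0.00144469
5.71250,5.85625,0.00123929
5.85625,6.00000,0.00106237
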