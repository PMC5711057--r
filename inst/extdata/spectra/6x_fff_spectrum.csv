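# 6X FFF 6 MV energy spectrum (parametric preset)
# columns: energy_lo,energy_hi,fluence (MeV, relative)
energy_lo,energy_hi,fluence
0.15000,0.29625,3.52879e-02
0.29625,0.44250,8.17117e-02
0.44250,0.58875,1.02319e-01
0.58875,0.73500,1.07219e-01
0.73500,0.88125,1.03053e-01
0.88125,1.02750,9.41044e-02
1.02750,1.17375,8.30666e-02
1.17375,1.32000,7.15749e-02
1.32000,1.46625,6.05694e-02
1.46625,1.61250,5.05427e-02
1.61250,1.75875,4.17060e-02
1.75875,1.90500,3.41008e-02
1.90500,2.05125,2.76706e-02
2.05125,2.19750,2.23087e-02
2.19750,2.34375,1.78868e-02
2.34375,2.49000,1.42729e-02
2.49000,2.63625,1.13416e-02
2.63625,2.78250,8.97911e-03
2.78250,2.92875,7.08547e-03
2.92875,3.07500,5.57480e-03
3.07500,3.22125,4.37466e-03
3.22125,3.36750,3.42469e-03
3.36750,3.51375,2.67520e-03
3.51375,3.66000,2.08560e-03
3.66000,3.80625,1.62299e-03
3.80625,3.95250,1.26089e-03
3.95250,4.09875,9.78062e-04
4.09875,4.24500,7.57594e-04
4.24500,4.39125,5.86045e-04
4.39125,4.53750,4.52782e-04
4.53750,4.68375,3.49420e-04
4.68375,4.83000,2.69363e-04
4.83000,4.97625,2.07439e-04
4.97625,5.12250,1.59599e-04
5.12250,5.26875,1.22683e-04
5.26875,5.41500,9.42258e-05
5.41500,5.56125,7.23121e-05
5.56125,5.70750,5.54532e-05
5.70750,5.85375,4.24944e-05
5.85375,6.00000,3.25420e-05
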