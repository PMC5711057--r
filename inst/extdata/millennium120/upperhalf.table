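# upper half leaf thickness vs cross-leaf position
# columns: leaf_number  y_breakpoint_cm  thickness_cm
1  -10.829250  3.3500
1  -10.328250  3.3300
1  -10.298250  0.0000
2  -10.286750  3.3500
2  -9.785750  3.3300
2  -9.755750  0.0000
3  -9.744250  3.3500
3  -9.243250  3.3300
3  -9.213250  0.0000
4  -9.201750  3.3500
4  -8.700750  3.3300
4  -8.670750  0.0000
5  -8.659250  3.3500
5  -8.158250  3.3300
5  -8.128250  0.0000
6  -8.116750  3.3500
6  -7.615750  3.3300
6  -7.585750  0.0000
7  -7.574250  3.3500
7  -7.073250  3.3300
7  -7.043250  0.0000
8  -7.031750  3.3500
8  -6.530750  3.3300
8  -6.500750  0.0000
9  -6.489250  3.3500
9  -5.988250  3.3300
9  -5.958250  0.0000
10  -5.946750  3.3500
10  -5.445750  3.3300
10  -5.415750  0.0000
11  -5.404250  3.3500
11  -5.174500  3.3300
11  -5.144500  0.0000
12  -5.133000  3.3500
12  -4.903250  3.3300
12  -4.873250  0.0000
13  -4.861750  3.3500
13  -4.632000  3.3300
13  -4.602000  0.0000
14  -4.590500  3.3500
14  -4.360750  3.3300
14  -4.330750  0.0000
15  -4.319250  3.3500
15  -4.089500  3.3300
15  -4.059500  0.0000
16  -4.048000  3.3500
16  -3.818250  3.3300
16  -3.788250  0.0000
17  -3.776750  3.3500
17  -3.547000  3.3300
17  -3.517000  0.0000
18  -3.505500  3.3500
18  -3.275750  3.3300
18  -3.245750  0.0000
19  -3.234250  3.3500
19  -3.004500  3.3300
19  -2.974500  0.0000
20  -2.963000  3.3500
20  -2.733250  3.3300
20  -2.703250  0.0000
21  -2.691750  3.3500
21  -2.462000  3.3300
21  -2.432000  0.0000
22  -2.420500  3.3500
22  -2.190750  3.3300
22  -2.160750  0.0000
23  -2.149250  3.3500
23  -1.919500  3.3300
23  -1.889500  0.0000
24  -1.878000  3.3500
24  -1.648250  3.3300
24  -1.618250  0.0000
25  -1.606750  3.3500
25  -1.377000  3.3300
25  -1.347000  0.0000
26  -1.335500  3.3500
26  -1.105750  3.3300
26  -1.075750  0.0000
27  -1.064250  3.3500
27  -0.834500  3.3300
27  -0.804500  0.0000
28  -0.793000  3.3500
28  -0.563250  3.3300
28  -0.533250  0.0000
29  -0.521750  3.3500
29  -0.292000  3.3300
29  -0.262000  0.0000
30  -0.250500  3.3500
30  -0.020750  3.3300
30  0.009250  0.0000
31  0.020750  3.3500
31  0.250500  3.3300
31  0.280500  0.0000
32  0.292000  3.3500
32  0.521750  3.3300
32  0.551750  0.0000
33  0.563250  3.3500
33  0.793000  3.3300
33  0.823000  0.0000
34  0.834500  3.3500
34  1.064250  3.3300
34  1.094250  0.0000
35  1.105750  3.3500
35  1.335500  3.3300
35  1.365500  0.0000
36  1.377000  3.3500
36  1.606750  3.3300
36  1.636750  0.0000
37  1.648250  3.3500
37  1.878000  3.3300
37  1.908000  0.0000
38  1.919500  3.3500
38  2.149250  3.3300
38  2.179250  0.0000
39  2.190750  3.3500
39  2.420500  3.3300
39  2.450500  0.0000
40  2.462000  3.3500
40  2.691750  3.3300
40  2.721750  0.0000
41  2.733250  3.3500
41  2.963000  3.3300
41  2.993000  0.0000
42  3.004500  3.3500
42  3.234250  3.3300
42  3.264250  0.0000
43  3.275750  3.3500
43  3.505500  3.3300
43  3.535500  0.0000
44  3.547000  3.3500
44  3.776750  3.3300
44  3.806750  0.0000
45  3.818250  3.3500
45  4.048000  3.3300
45  4.078000  0.0000
46  4.089500  3.3500
46  4.319250  3.3300
46  4.349250  0.0000
47  4.360750  3.3500
47  4.590500  3.3300
47  4.620500  0.0000
48  4.632000  3.3500
48  4.861750  3.3300
48  4.891750  0.0000
49  4.903250  3.3500
49  5.133000  3.3300
49  5.163000  0.0000
50  5.174500  3.3500
50  5.404250  3.3300
50  5.434250  0.0000
51  5.445750  3.3500
51  5.946750  3.3300
51  5.976750  0.0000
52  5.988250  3.3500
52  6.489250  3.3300
52  6.519250  0.0000
53  6.530750  3.3500
53  7.031750  3.3300
53  7.061750  0.0000
54  7.073250  3.3500
54  7.574250  3.3300
54  7.604250  0.0000
55  7.615750  3.3500
55  8.116750  3.3300
55  8.146750  0.0000
56  8.158250  3.3500
56  8.659250  3.3300
56  8.689250  0.0000
57  8.700750  3.3500
57  9.201750  3.3300
57  9.231750  0.0000
58  9.243250  3.3500
58  9.744250  3.3300
58  9.774250  0.0000
59  9.785750  3.3500
59  10.286750  3.3300
59  10.316750  0.0000
60  10.328250  3.3500
60  10.829250  3.3300
60  10.859250  0.0000
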