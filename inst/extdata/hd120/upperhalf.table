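# upper half leaf thickness vs cross-leaf position
# columns: leaf_number  y_breakpoint_cm  thickness_cm
1  -5.957750  3.4500
1  -5.727500  3.4300
1  -5.697500  0.0000
2  -5.686000  3.4500
2  -5.455750  3.4300
2  -5.425750  0.0000
3  -5.414250  3.4500
3  -5.184000  3.4300
3  -5.154000  0.0000
4  -5.142500  3.4500
4  -4.912250  3.4300
4  -4.882250  0.0000
5  -4.870750  3.4500
5  -4.640500  3.4300
5  -4.610500  0.0000
6  -4.599000  3.4500
6  -4.368750  3.4300
6  -4.338750  0.0000
7  -4.327250  3.4500
7  -4.097000  3.4300
7  -4.067000  0.0000
8  -4.055500  3.4500
8  -3.825250  3.4300
8  -3.795250  0.0000
9  -3.783750  3.4500
9  -3.553500  3.4300
9  -3.523500  0.0000
10  -3.512000  3.4500
10  -3.281750  3.4300
10  -3.251750  0.0000
11  -3.240250  3.4500
11  -3.010000  3.4300
11  -2.980000  0.0000
12  -2.968500  3.4500
12  -2.738250  3.4300
12  -2.708250  0.0000
13  -2.696750  3.4500
13  -2.466500  3.4300
13  -2.436500  0.0000
14  -2.425000  3.4500
14  -2.194750  3.4300
14  -2.164750  0.0000
15  -2.153250  3.4500
15  -2.058875  3.4300
15  -2.028875  0.0000
16  -2.017375  3.4500
16  -1.923000  3.4300
16  -1.893000  0.0000
17  -1.881500  3.4500
17  -1.787125  3.4300
17  -1.757125  0.0000
18  -1.745625  3.4500
18  -1.651250  3.4300
18  -1.621250  0.0000
19  -1.609750  3.4500
19  -1.515375  3.4300
19  -1.485375  0.0000
20  -1.473875  3.4500
20  -1.379500  3.4300
20  -1.349500  0.0000
21  -1.338000  3.4500
21  -1.243625  3.4300
21  -1.213625  0.0000
22  -1.202125  3.4500
22  -1.107750  3.4300
22  -1.077750  0.0000
23  -1.066250  3.4500
23  -0.971875  3.4300
23  -0.941875  0.0000
24  -0.930375  3.4500
24  -0.836000  3.4300
24  -0.806000  0.0000
25  -0.794500  3.4500
25  -0.700125  3.4300
25  -0.670125  0.0000
26  -0.658625  3.4500
26  -0.564250  3.4300
26  -0.534250  0.0000
27  -0.522750  3.4500
27  -0.428375  3.4300
27  -0.398375  0.0000
28  -0.386875  3.4500
28  -0.292500  3.4300
28  -0.262500  0.0000
29  -0.251000  3.4500
29  -0.156625  3.4300
29  -0.126625  0.0000
30  -0.115125  3.4500
30  -0.020750  3.4300
30  0.009250  0.0000
31  0.020750  3.4500
31  0.115125  3.4300
31  0.145125  0.0000
32  0.156625  3.4500
32  0.251000  3.4300
32  0.281000  0.0000
33  0.292500  3.4500
33  0.386875  3.4300
33  0.416875  0.0000
34  0.428375  3.4500
34  0.522750  3.4300
34  0.552750  0.0000
35  0.564250  3.4500
35  0.658625  3.4300
35  0.688625  0.0000
36  0.700125  3.4500
36  0.794500  3.4300
36  0.824500  0.0000
37  0.836000  3.4500
37  0.930375  3.4300
37  0.960375  0.0000
38  0.971875  3.4500
38  1.066250  3.4300
38  1.096250  0.0000
39  1.107750  3.4500
39  1.202125  3.4300
39  1.232125  0.0000
40  1.243625  3.4500
40  1.338000  3.4300
40  1.368000  0.0000
41  1.379500  3.4500
41  1.473875  3.4300
41  1.503875  0.0000
42  1.515375  3.4500
42  1.609750  3.4300
42  1.639750  0.0000
43  1.651250  3.4500
43  1.745625  3.4300
43  1.775625  0.0000
44  1.787125  3.4500
44  1.881500  3.4300
44  1.911500  0.0000
45  1.923000  3.4500
45  2.017375  3.4300
45  2.047375  0.0000
46  2.058875  3.4500
46  2.153250  3.4300
46  2.183250  0.0000
47  2.194750  3.4500
47  2.425000  3.4300
47  2.455000  0.0000
48  2.466500  3.4500
48  2.696750  3.4300
48  2.726750  0.0000
49  2.738250  3.4500
49  2.968500  3.4300
49  2.998500  0.0000
50  3.010000  3.4500
50  3.240250  3.4300
50  3.270250  0.0000
51  3.281750  3.4500
51  3.512000  3.4300
51  3.542000  0.0000
52  3.553500  3.4500
52  3.783750  3.4300
52  3.813750  0.0000
53  3.825250  3.4500
53  4.055500  3.4300
53  4.085500  0.0000
54  4.097000  3.4500
54  4.327250  3.4300
54  4.357250  0.0000
55  4.368750  3.4500
55  4.599000  3.4300
55  4.629000  0.0000
56  4.640500  3.4500
56  4.870750  3.4300
56  4.900750  0.0000
57  4.912250  3.4500
57  5.142500  3.4300
57  5.172500  0.0000
58  5.184000  3.4500
58  5.414250  3.4300
58  5.444250  0.0000
59  5.455750  3.4500
59  5.686000  3.4300
59  5.716000  0.0000
60  5.727500  3.4500
60  5.957750  3.4300
60  5.987750  0.0000
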