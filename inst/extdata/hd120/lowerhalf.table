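# lower half leaf thickness vs cross-leaf position
# columns: leaf_number  y_breakpoint_cm  thickness_cm
1  -5.987750  3.4300
1  -5.957750  3.4500
1  -5.727500  0.0000
2  -5.716000  3.4300
2  -5.686000  3.4500
2  -5.455750  0.0000
3  -5.444250  3.4300
3  -5.414250  3.4500
3  -5.184000  0.0000
4  -5.172500  3.4300
4  -5.142500  3.4500
4  -4.912250  0.0000
5  -4.900750  3.4300
5  -4.870750  3.4500
5  -4.640500  0.0000
6  -4.629000  3.4300
6  -4.599000  3.4500
6  -4.368750  0.0000
7  -4.357250  3.4300
7  -4.327250  3.4500
7  -4.097000  0.0000
8  -4.085500  3.4300
8  -4.055500  3.4500
8  -3.825250  0.0000
9  -3.813750  3.4300
9  -3.783750  3.4500
9  -3.553500  0.0000
10  -3.542000  3.4300
10  -3.512000  3.4500
10  -3.281750  0.0000
11  -3.270250  3.4300
11  -3.240250  3.4500
11  -3.010000  0.0000
12  -2.998500  3.4300
12  -2.968500  3.4500
12  -2.738250  0.0000
13  -2.726750  3.4300
13  -2.696750  3.4500
13  -2.466500  0.0000
14  -2.455000  3.4300
14  -2.425000  3.4500
14  -2.194750  0.0000
15  -2.183250  3.4300
15  -2.153250  3.4500
15  -2.058875  0.0000
16  -2.047375  3.4300
16  -2.017375  3.4500
16  -1.923000  0.0000
17  -1.911500  3.4300
17  -1.881500  3.4500
17  -1.787125  0.0000
18  -1.775625  3.4300
18  -1.745625  3.4500
18  -1.651250  0.0000
19  -1.639750  3.4300
19  -1.609750  3.4500
19  -1.515375  0.0000
20  -1.503875  3.4300
20  -1.473875  3.4500
20  -1.379500  0.0000
21  -1.368000  3.4300
21  -1.338000  3.4500
21  -1.243625  0.0000
22  -1.232125  3.4300
22  -1.202125  3.4500
22  -1.107750  0.0000
23  -1.096250  3.4300
23  -1.066250  3.4500
23  -0.971875  0.0000
24  -0.960375  3.4300
24  -0.930375  3.4500
24  -0.836000  0.0000
25  -0.824500  3.4300
25  -0.794500  3.4500
25  -0.700125  0.0000
26  -0.688625  3.4300
26  -0.658625  3.4500
26  -0.564250  0.0000
27  -0.552750  3.4300
27  -0.522750  3.4500
27  -0.428375  0.0000
28  -0.416875  3.4300
28  -0.386875  3.4500
28  -0.292500  0.0000
29  -0.281000  3.4300
29  -0.251000  3.4500
29  -0.156625  0.0000
30  -0.145125  3.4300
30  -0.115125  3.4500
30  -0.020750  0.0000
31  -0.009250  3.4300
31  0.020750  3.4500
31  0.115125  0.0000
32  0.126625  3.4300
32  0.156625  3.4500
32  0.251000  0.0000
33  0.262500  3.4300
33  0.292500  3.4500
33  0.386875  0.0000
34  0.398375  3.4300
34  0.428375  3.4500
34  0.522750  0.0000
35  0.534250  3.4300
35  0.564250  3.4500
35  0.658625  0.0000
36  0.670125  3.4300
36  0.700125  3.4500
36  0.794500  0.0000
37  0.806000  3.4300
37  0.836000  3.4500
37  0.930375  0.0000
38  0.941875  3.4300
38  0.971875  3.4500
38  1.066250  0.0000
39  1.077750  3.4300
39  1.107750  3.4500
39  1.202125  0.0000
40  1.213625  3.4300
40  1.243625  3.4500
40  1.338000  0.0000
41  1.349500  3.4300
41  1.379500  3.4500
41  1.473875  0.0000
42  1.485375  3.4300
42  1.515375  3.4500
42  1.609750  0.0000
43  1.621250  3.4300
43  1.651250  3.4500
43  1.745625  0.0000
44  1.757125  3.4300
44  1.787125  3.4500
44  1.881500  0.0000
45  1.893000  3.4300
45  1.923000  3.4500
45  2.017375  0.0000
46  2.028875  3.4300
46  2.058875  3.4500
46  2.153250  0.0000
47  2.164750  3.4300
47  2.194750  3.4500
47  2.425000  0.0000
48  2.436500  3.4300
48  2.466500  3.4500
48  2.696750  0.0000
49  2.708250  3.4300
49  2.738250  3.4500
49  2.968500  0.0000
50  2.980000  3.4300
50  3.010000  3.4500
50  3.240250  0.0000
51  3.251750  3.4300
51  3.281750  3.4500
51  3.512000  0.0000
52  3.523500  3.4300
52  3.553500  3.4500
52  3.783750  0.0000
53  3.795250  3.4300
53  3.825250  3.4500
53  4.055500  0.0000
54  4.067000  3.4300
54  4.097000  3.4500
54  4.327250  0.0000
55  4.338750  3.4300
55  4.368750  3.4500
55  4.599000  0.0000
56  4.610500  3.4300
56  4.640500  3.4500
56  4.870750  0.0000
57  4.882250  3.4300
57  4.912250  3.4500
57  5.142500  0.0000
58  5.154000  3.4300
58  5.184000  3.4500
58  5.414250  0.0000
59  5.425750  3.4300
59  5.455750  3.4500
59  5.686000  0.0000
60  5.697500  3.4300
60  5.727500  3.4500
60  5.957750  0.0000
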