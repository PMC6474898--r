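# fadseed schema grid_events v1
"event_index","time","row","col"
1,1,0,0
2,2,2,0
3,3,4,0
4,4,1,0
5,5,6,0
6,6,1,1
7,7,3,1
8,8,3,0
9,9,5,1
10,10,7,1
11,11,0,2
12,12,5,0
13,13,2,2
14,14,4,2
15,15,6,2
16,16,7,0
17,17,1,3
18,18,3,3
19,19,5,3
20,20,0,1
21,21,7,3
22,22,0,4
23,23,2,4
24,24,2,1
25,25,4,4
26,26,6,4
27,27,1,5
28,28,4,1
29,29,3,5
30,30,5,5
31,31,7,5
32,32,6,1
33,33,0,6
34,34,1,2
35,35,3,2
36,36,5,2
37,37,2,6
38,38,7,2
39,39,0,3
40,40,2,3
41,41,4,6
42,42,4,3
43,43,6,3
44,44,1,4
45,45,6,6
46,46,3,4
47,47,5,4
48,48,7,4
49,49,1,7
50,50,0,5
51,51,2,5
52,52,4,5
53,53,3,7
54,54,6,5
55,55,1,6
56,56,3,6
57,57,5,7
58,58,5,6
59,59,7,6
60,60,0,7
61,61,7,7
62,62,2,7
63,63,4,7
64,64,6,7
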