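# fadseed schema trials v1
"trial_id","session","time","removed_category"
1,"session_1",1,"unspotted"
2,"session_1",2,"spotted"
3,"session_1",3,"unspotted"
4,"session_1",4,"unspotted"
5,"session_1",5,"spotted"
6,"session_1",6,"unspotted"
7,"session_1",7,"spotted"
8,"session_1",8,"unspotted"
9,"session_1",9,"spotted"
10,"session_1",10,"unspotted"
11,"session_1",11,"unspotted"
12,"session_1",12,"spotted"
13,"session_1",13,"unspotted"
14,"session_1",14,"spotted"
15,"session_1",15,"unspotted"
16,"session_1",16,"unspotted"
17,"session_1",17,"spotted"
18,"session_1",18,"unspotted"
19,"session_1",19,"spotted"
20,"session_1",20,"unspotted"
21,"session_1",21,"unspotted"
22,"session_1",22,"spotted"
23,"session_1",23,"unspotted"
24,"session_1",24,"spotted"
25,"session_1",25,"unspotted"
26,"session_1",26,"spotted"
27,"session_1",27,"unspotted"
28,"session_1",28,"unspotted"
29,"session_1",29,"spotted"
30,"session_1",30,"unspotted"
31,"session_2",1,"unspotted"
32,"session_2",2,"spotted"
33,"session_2",3,"unspotted"
34,"session_2",4,"unspotted"
35,"session_2",5,"spotted"
36,"session_2",6,"unspotted"
37,"session_2",7,"spotted"
38,"session_2",8,"unspotted"
39,"session_2",9,"spotted"
40,"session_2",10,"unspotted"
41,"session_2",11,"spotted"
42,"session_2",12,"unspotted"
43,"session_2",13,"unspotted"
44,"session_2",14,"spotted"
45,"session_2",15,"unspotted"
46,"session_3",1,"unspotted"
47,"session_3",2,"spotted"
48,"session_3",3,"unspotted"
49,"session_3",4,"unspotted"
50,"session_3",5,"spotted"
51,"session_3",6,"unspotted"
52,"session_3",7,"spotted"
53,"session_3",8,"unspotted"
54,"session_3",9,"unspotted"
55,"session_3",10,"spotted"
56,"session_3",11,"unspotted"
57,"session_3",12,"spotted"
58,"session_3",13,"unspotted"
59,"session_3",14,"unspotted"
60,"session_3",15,"spotted"
61,"session_3",16,"unspotted"
62,"session_3",17,"unspotted"
63,"session_3",18,"spotted"
64,"session_3",19,"unspotted"
65,"session_3",20,"spotted"
66,"session_3",21,"unspotted"
67,"session_3",22,"unspotted"
68,"session_3",23,"spotted"
69,"session_3",24,"unspotted"
70,"session_3",25,"spotted"
71,"session_3",26,"unspotted"
72,"session_3",27,"unspotted"
73,"session_3",28,"spotted"
74,"session_3",29,"unspotted"
75,"session_3",30,"spotted"
76,"session_3",31,"unspotted"
77,"session_3",32,"unspotted"
78,"session_3",33,"spotted"
79,"session_3",34,"unspotted"
80,"session_3",35,"spotted"
81,"session_3",36,"unspotted"
82,"session_3",37,"unspotted"
83,"session_3",38,"spotted"
84,"session_3",39,"unspotted"
85,"session_3",40,"unspotted"
86,"session_3",41,"spotted"
87,"session_3",42,"unspotted"
88,"session_3",43,"spotted"
89,"session_3",44,"unspotted"
90,"session_3",45,"unspotted"
91,"session_3",46,"spotted"
92,"session_3",47,"unspotted"
93,"session_3",48,"spotted"
94,"session_3",49,"unspotted"
95,"session_3",50,"unspotted"
96,"session_3",51,"spotted"
97,"session_3",52,"unspotted"
98,"session_3",53,"spotted"
99,"session_3",54,"unspotted"
100,"session_3",55,"unspotted"
101,"session_3",56,"spotted"
102,"session_3",57,"unspotted"
103,"session_3",58,"spotted"
104,"session_3",59,"unspotted"
105,"session_3",60,"unspotted"
106,"session_3",61,"spotted"
107,"session_3",62,"unspotted"
108,"session_3",63,"unspotted"
109,"session_3",64,"spotted"
110,"session_3",65,"unspotted"
111,"session_3",66,"spotted"
112,"session_3",67,"unspotted"
113,"session_3",68,"unspotted"
114,"session_3",69,"spotted"
115,"session_3",70,"unspotted"
116,"session_3",71,"spotted"
117,"session_3",72,"unspotted"
118,"session_3",73,"unspotted"
119,"session_3",74,"spotted"
120,"session_3",75,"unspotted"
121,"session_3",76,"spotted"
122,"session_3",77,"unspotted"
123,"session_3",78,"unspotted"
124,"session_3",79,"spotted"
125,"session_3",80,"unspotted"
126,"session_3",81,"spotted"
127,"session_3",82,"unspotted"
128,"session_3",83,"unspotted"
129,"session_3",84,"spotted"
130,"session_3",85,"unspotted"
131,"session_3",86,"unspotted"
132,"session_3",87,"spotted"
133,"session_3",88,"unspotted"
134,"session_3",89,"spotted"
135,"session_3",90,"unspotted"
136,"session_3",91,"unspotted"
137,"session_3",92,"spotted"
138,"session_3",93,"unspotted"
139,"session_3",94,"spotted"
140,"session_3",95,"unspotted"
141,"session_3",96,"unspotted"
142,"session_3",97,"spotted"
143,"session_3",98,"unspotted"
144,"session_3",99,"spotted"
145,"session_3",100,"unspotted"
146,"session_3",101,"unspotted"
147,"session_3",102,"spotted"
148,"session_3",103,"unspotted"
149,"session_3",104,"spotted"
150,"session_3",105,"unspotted"
151,"session_3",106,"unspotted"
152,"session_3",107,"spotted"
153,"session_3",108,"unspotted"
154,"session_3",109,"unspotted"
155,"session_3",110,"spotted"
156,"session_3",111,"unspotted"
157,"session_3",112,"spotted"
158,"session_3",113,"unspotted"
159,"session_3",114,"unspotted"
160,"session_3",115,"spotted"
161,"session_3",116,"unspotted"
162,"session_3",117,"spotted"
163,"session_3",118,"unspotted"
164,"session_3",119,"unspotted"
165,"session_3",120,"spotted"
166,"session_3",121,"unspotted"
167,"session_3",122,"spotted"
168,"session_3",123,"unspotted"
169,"session_3",124,"unspotted"
170,"session_3",125,"spotted"
171,"session_3",126,"unspotted"
172,"session_3",127,"spotted"
173,"session_3",128,"unspotted"
174,"session_3",129,"unspotted"
175,"session_3",130,"spotted"
176,"session_3",131,"unspotted"
177,"session_3",132,"unspotted"
178,"session_3",133,"spotted"
179,"session_3",134,"unspotted"
180,"session_3",135,"spotted"
181,"session_3",136,"unspotted"
182,"session_3",137,"unspotted"
183,"session_3",138,"spotted"
184,"session_3",139,"unspotted"
185,"session_3",140,"spotted"
186,"session_3",141,"unspotted"
187,"session_3",142,"unspotted"
188,"session_3",143,"spotted"
189,"session_3",144,"unspotted"
190,"session_3",145,"spotted"
191,"session_3",146,"unspotted"
192,"session_3",147,"unspotted"
193,"session_3",148,"spotted"
194,"session_3",149,"unspotted"
195,"session_3",150,"spotted"
196,"session_3",151,"unspotted"
197,"session_3",152,"unspotted"
198,"session_3",153,"spotted"
199,"session_3",154,"unspotted"
200,"session_3",155,"unspotted"
201,"session_3",156,"spotted"
202,"session_3",157,"unspotted"
203,"session_3",158,"spotted"
204,"session_3",159,"unspotted"
205,"session_3",160,"unspotted"
206,"session_3",161,"spotted"
207,"session_3",162,"unspotted"
208,"session_3",163,"spotted"
209,"session_3",164,"unspotted"
210,"session_3",165,"unspotted"
211,"session_3",166,"spotted"
212,"session_3",167,"unspotted"
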