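1	2
1	9
1	16
2	3
2	4
2	8
4	5
4	6
4	7
9	10
9	11
9	12
12	13
12	14
12	15
16	17
16	18
16	21
18	19
18	20
21	22
21	24
21	27
22	23
24	25
24	26
27	28

1	a
2	a
3	b
4	c
5	a
6	c
7	b
8	d
9	a
10	d
11	b
12	c
13	b
14	c
15	a
16	b
17	a
18	b
19	b
20	c
21	a
22	a
23	d
24	b
25	b
26	c
27	a
28	d
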