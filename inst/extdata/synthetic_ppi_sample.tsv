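1	2
1	3
1	4
1	5
1	6
1	7
1	8
1	11
1	12
1	13
1	15
1	16
1	18
1	21
1	28
1	29
1	31
1	32
1	33
1	34
1	37
1	39
1	40
1	41
1	68
1	74
1	75
1	76
1	80
1	83
1	91
1	94
1	98
1	100
1	109
1	113
2	3
2	4
2	5
2	6
2	7
2	11
2	12
2	13
2	15
2	16
2	17
2	21
2	22
2	24
2	26
2	38
2	43
2	51
2	56
2	57
2	63
2	66
2	84
2	95
2	100
3	4
3	12
3	26
3	45
3	51
3	64
3	74
3	85
3	106
4	5
4	6
4	8
4	9
4	10
4	14
4	15
4	18
4	19
4	20
4	25
4	26
4	42
4	44
4	45
4	50
4	55
4	58
4	67
4	80
4	83
4	85
4	88
4	92
4	93
4	98
4	99
4	104
4	107
4	108
4	110
4	113
5	7
5	8
5	11
5	17
5	20
5	22
5	27
5	31
5	34
5	35
5	50
5	54
5	70
5	78
5	86
5	120
6	9
6	10
6	36
6	53
7	9
7	16
7	23
7	25
7	29
7	35
7	38
7	40
7	47
7	49
7	95
7	103
7	111
7	114
7	117
8	19
8	27
8	29
8	52
8	65
8	89
8	107
8	119
9	10
9	14
9	23
9	35
9	50
9	52
9	55
9	65
9	69
9	74
9	75
9	90
9	97
10	20
10	44
10	53
10	59
11	13
11	33
11	46
12	24
12	34
12	42
12	43
12	45
12	64
12	69
12	77
12	105
12	116
13	14
13	22
13	27
13	30
13	33
13	40
13	46
13	48
13	72
13	94
13	108
13	112
14	23
14	46
14	56
14	59
14	73
14	80
14	106
15	19
15	42
15	61
15	88
15	108
16	17
16	18
16	38
16	57
16	66
16	71
16	86
16	91
16	94
16	115
16	118
16	119
17	37
17	54
17	60
17	115
18	24
18	28
18	43
18	48
18	49
18	63
19	52
19	101
20	21
20	25
20	28
20	41
20	53
20	85
20	99
20	102
21	87
22	30
22	31
22	32
22	48
22	70
22	77
22	78
22	82
22	120
23	98
24	36
24	66
24	73
24	114
26	51
26	57
26	58
26	93
26	117
27	62
28	41
29	30
29	39
29	44
29	58
29	60
29	82
29	103
29	109
29	111
29	114
30	36
31	32
31	39
31	62
31	68
31	71
31	75
32	54
32	55
33	72
33	79
34	37
34	116
35	47
35	61
35	71
35	78
35	84
37	59
37	70
37	81
37	83
37	88
37	96
38	47
38	76
38	112
38	118
38	119
39	62
39	109
39	111
42	69
42	105
43	49
43	56
43	104
44	81
44	101
45	64
45	67
45	116
47	61
48	63
48	99
50	91
51	92
51	93
51	107
52	65
52	89
52	100
53	60
53	68
53	81
56	104
56	118
58	67
58	79
58	110
58	117
59	73
60	87
60	102
63	87
65	90
67	86
68	72
70	82
70	90
70	96
71	84
72	79
74	77
74	106
75	76
75	97
77	92
77	101
80	89
82	96
82	103
82	120
84	105
88	110
89	97
94	95
99	102
100	112
100	115
111	113
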