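age,sex,race,ex
18,male,all,58.28
19,male,all,57.38
20,male,all,56.48
21,male,all,55.58
22,male,all,54.68
23,male,all,53.78
24,male,all,52.88
25,male,all,51.97
26,male,all,51.07
27,male,all,50.17
28,male,all,49.27
29,male,all,48.37
30,male,all,47.47
31,male,all,46.6
32,male,all,45.72
33,male,all,44.85
34,male,all,43.97
35,male,all,43.1
36,male,all,42.22
37,male,all,41.35
38,male,all,40.48
39,male,all,39.6
40,male,all,38.73
41,male,all,37.89
42,male,all,37.05
43,male,all,36.22
44,male,all,35.38
45,male,all,34.54
46,male,all,33.71
47,male,all,32.87
48,male,all,32.04
49,male,all,31.2
50,male,all,30.36
51,male,all,29.54
52,male,all,28.72
53,male,all,27.9
54,male,all,27.08
55,male,all,26.26
56,male,all,25.44
57,male,all,24.62
58,male,all,23.79
59,male,all,22.97
60,male,all,22.15
61,male,all,21.33
62,male,all,20.51
63,male,all,19.69
64,male,all,18.87
65,male,all,18.05
66,male,all,17.4
67,male,all,16.75
68,male,all,16.1
69,male,all,15.45
70,male,all,14.8
71,male,all,14.16
72,male,all,13.51
73,male,all,12.86
74,male,all,12.21
75,male,all,11.56
76,male,all,11.02
77,male,all,10.47
78,male,all,9.93
79,male,all,9.38
80,male,all,8.84
81,male,all,8.29
82,male,all,7.75
83,male,all,7.2
84,male,all,6.66
85,male,all,6.11
86,male,all,5.81
87,male,all,5.51
88,male,all,5.21
89,male,all,4.91
90,male,all,4.61
91,male,all,4.31
92,male,all,4
93,male,all,3.7
94,male,all,3.4
95,male,all,3.1
96,male,all,2.99
97,male,all,2.88
98,male,all,2.76
99,male,all,2.65
100,male,all,2.54
101,male,all,2.43
102,male,all,2.31
103,male,all,2.2
104,male,all,2.09
105,male,all,1.97
106,male,all,1.86
107,male,all,1.75
108,male,all,1.64
109,male,all,1.52
110,male,all,1.41
18,female,all,65.72
19,female,all,64.7
20,female,all,63.69
21,female,all,62.67
22,female,all,61.66
23,female,all,60.64
24,female,all,59.62
25,female,all,58.61
26,female,all,57.59
27,female,all,56.58
28,female,all,55.56
29,female,all,54.55
30,female,all,53.53
31,female,all,52.54
32,female,all,51.56
33,female,all,50.57
34,female,all,49.59
35,female,all,48.6
36,female,all,47.62
37,female,all,46.63
38,female,all,45.64
39,female,all,44.66
40,female,all,43.67
41,female,all,42.73
42,female,all,41.79
43,female,all,40.84
44,female,all,39.9
45,female,all,38.96
46,female,all,38.01
47,female,all,37.07
48,female,all,36.12
49,female,all,35.18
50,female,all,34.24
51,female,all,33.31
52,female,all,32.39
53,female,all,31.46
54,female,all,30.54
55,female,all,29.61
56,female,all,28.68
57,female,all,27.76
58,female,all,26.83
59,female,all,25.91
60,female,all,24.98
61,female,all,24.05
62,female,all,23.13
63,female,all,22.2
64,female,all,21.28
65,female,all,20.35
66,female,all,19.62
67,female,all,18.89
68,female,all,18.16
69,female,all,17.43
70,female,all,16.7
71,female,all,15.96
72,female,all,15.23
73,female,all,14.5
74,female,all,13.77
75,female,all,13.04
76,female,all,12.42
77,female,all,11.81
78,female,all,11.19
79,female,all,10.58
80,female,all,9.96
81,female,all,9.35
82,female,all,8.73
83,female,all,8.12
84,female,all,7.5
85,female,all,6.89
86,female,all,6.55
87,female,all,6.21
88,female,all,5.87
89,female,all,5.53
90,female,all,5.19
91,female,all,4.85
92,female,all,4.52
93,female,all,4.18
94,female,all,3.84
95,female,all,3.5
96,female,all,3.37
97,female,all,3.24
98,female,all,3.12
99,female,all,2.99
100,female,all,2.86
101,female,all,2.73
102,female,all,2.61
103,female,all,2.48
104,female,all,2.35
105,female,all,2.23
106,female,all,2.1
107,female,all,1.97
108,female,all,1.84
109,female,all,1.72
110,female,all,1.59
18,all,all,62
19,all,all,61.04
20,all,all,60.08
21,all,all,59.12
22,all,all,58.17
23,all,all,57.21
24,all,all,56.25
25,all,all,55.29
26,all,all,54.33
27,all,all,53.38
28,all,all,52.42
29,all,all,51.46
30,all,all,50.5
31,all,all,49.57
32,all,all,48.64
33,all,all,47.71
34,all,all,46.78
35,all,all,45.85
36,all,all,44.92
37,all,all,43.99
38,all,all,43.06
39,all,all,42.13
40,all,all,41.2
41,all,all,40.31
42,all,all,39.42
43,all,all,38.53
44,all,all,37.64
45,all,all,36.75
46,all,all,35.86
47,all,all,34.97
48,all,all,34.08
49,all,all,33.19
50,all,all,32.3
51,all,all,31.43
52,all,all,30.55
53,all,all,29.68
54,all,all,28.81
55,all,all,27.93
56,all,all,27.06
57,all,all,26.19
58,all,all,25.31
59,all,all,24.44
60,all,all,23.57
61,all,all,22.69
62,all,all,21.82
63,all,all,20.95
64,all,all,20.07
65,all,all,19.2
66,all,all,18.51
67,all,all,17.82
68,all,all,17.13
69,all,all,16.44
70,all,all,15.75
71,all,all,15.06
72,all,all,14.37
73,all,all,13.68
74,all,all,12.99
75,all,all,12.3
76,all,all,11.72
77,all,all,11.14
78,all,all,10.56
79,all,all,9.98
80,all,all,9.4
81,all,all,8.82
82,all,all,8.24
83,all,all,7.66
84,all,all,7.08
85,all,all,6.5
86,all,all,6.18
87,all,all,5.86
88,all,all,5.54
89,all,all,5.22
90,all,all,4.9
91,all,all,4.58
92,all,all,4.26
93,all,all,3.94
94,all,all,3.62
95,all,all,3.3
96,all,all,3.18
97,all,all,3.06
98,all,all,2.94
99,all,all,2.82
100,all,all,2.7
101,all,all,2.58
102,all,all,2.46
103,all,all,2.34
104,all,all,2.22
105,all,all,2.1
106,all,all,1.98
107,all,all,1.86
108,all,all,1.74
109,all,all,1.62
110,all,all,1.5
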