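timestamp,glucose_mgdl
0,96.3
300,96.8
600,99
900,99
1200,98.4
1500,99.3
1800,103.9
2100,98.3
2400,97.4
2700,101.8
3000,103.7
3300,99.2
3600,100.1
3900,101.6
4200,99.5
4500,101
4800,103.6
5100,101.1
5400,98.4
5700,105.8
6000,107
6300,107.9
6600,109.8
6900,108.5
7200,109.3
7500,106.9
7800,104.5
8100,105.4
8400,106.8
8700,101.7
9000,96.2
9300,99.3
9600,100.6
9900,100.5
10200,104.2
10500,102.9
10800,100.7
11100,99.8
11400,101.3
11700,100.3
12000,103.2
12300,109.2
12600,106.9
12900,104.7
13200,102.6
13500,104.3
13800,104.3
14100,102.2
14400,101.9
14700,104.4
15000,105.9
15300,104
15600,98
15900,102.5
16200,103.1
16500,102
16800,103.9
17100,103.7
17400,109.2
17700,105.9
18000,108.8
18300,106.6
18600,106.1
18900,106.1
19200,103.8
19500,102.2
19800,99.3
20100,100.1
20400,100.5
20700,101.5
21000,102
21300,100.4
21600,99.4
21900,100.8
22200,101.5
22500,100.6
22800,101.8
23100,103.5
23400,101.1
23700,98.9
24000,93.6
24300,96.4
24600,96.9
24900,96.7
25200,99.5
25500,96.3
25800,105.2
26100,113.9
26400,135.7
26700,163.6
27000,188.4
27300,209.8
27600,221.6
27900,218.9
28200,200.4
28500,176.1
28800,146.8
29100,120.8
29400,101.7
29700,93.3
30000,94.5
30300,92.8
30600,93.1
30900,95.7
31200,98.3
31500,99.3
31800,77
32100,49.3
32400,51.3
32700,48.5
33000,48.6
33300,47.5
33600,47.2
33900,43.8
34200,69.7
34500,91.3
34800,96.6
35100,93.8
35400,94.3
35700,94.5
36000,95.1
36300,91.8
36600,91.2
36900,90.9
37200,92.3
37500,92.9
37800,89.3
38100,88.5
38400,87.8
38700,88.7
39000,87.3
39300,90.7
39600,89.3
39900,86.2
40200,88.7
40500,89
40800,85.5
41100,84.8
41400,83.4
41700,97.5
42000,113.5
42300,131.2
42600,152.4
42900,174.9
43200,186.5
43500,193.5
43800,194.5
44100,191.2
44400,181
44700,167.8
45000,144.2
45300,124.7
45600,105.2
45900,94.6
46200,90.5
46500,91.9
46800,71.2
47100,40.1
47400,40
47700,42
48000,41.2
48300,75.5
48600,95.4
48900,93.8
49200,95.9
49500,99.8
49800,98.8
50100,100.8
50400,98.2
50700,99
51000,102
51300,96
51600,93.8
51900,99.9
52200,97.3
52500,105.2
52800,103.7
53100,107
53400,100.1
53700,98.7
54000,97.1
54300,99.9
54600,102
54900,104.8
55200,103.6
55500,102.8
55800,100.8
56100,101.4
56400,101.3
56700,100.9
57000,104.8
57300,111.2
57600,123.2
57900,135.7
58200,150.6
58500,161.1
58800,176.2
59100,180.9
59400,179.7
59700,175.1
60000,164.4
60300,155.1
60600,142
60900,130.4
61200,120.8
61500,108.1
61800,98.3
62100,97.6
62400,95.7
62700,97.5
63000,99.4
63300,95.9
63600,99.5
63900,102.9
64200,101.8
64500,101.6
64800,102.8
65100,105.1
65400,102.7
65700,105.6
66000,104
66300,103.9
66600,105.7
66900,101.9
67200,101.6
67500,98.5
67800,100.9
68100,102.3
68400,103.5
68700,98.1
69000,100.9
69300,100.8
69600,101.6
69900,105.6
70200,108.9
70500,118.1
70800,125.4
71100,135.5
71400,146.2
71700,158.8
72000,169.8
72300,178.2
72600,184
72900,188.7
73200,188.5
73500,184.8
73800,179.9
74100,171.5
74400,158.8
74700,151.6
75000,144.6
75300,133
75600,123.1
75900,119.1
76200,110
76500,109.8
76800,108.6
77100,104.8
77400,107.5
77700,110.9
78000,108.2
78300,105.5
78600,104.7
78900,101.8
79200,104.7
79500,106.2
79800,104.4
80100,108.5
80400,107.7
80700,103.1
81000,104.2
81300,103.7
81600,100.6
81900,98.8
82200,97.1
82500,102.6
82800,103.3
83100,101.8
83400,101.5
83700,101.9
84000,102.8
84300,101.8
84600,102.8
84900,103.7
85200,102.3
85500,101.3
85800,97.4
86100,98.1
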