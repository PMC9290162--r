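sample	method	label	vaf_percent
1	sanger	T315I	NA
1	lrsms	T315I	96.8
1	lrsms	F359C	2.1
1	lrsms	H396R	1.2
2	sanger	F359I	NA
2	sanger	T315I	NA
2	lrsms	F359I	84.9
2	lrsms	T315I	14.4
3	sanger	-	NA
3	lrsms	M244V	0.6
4	sanger	Y253H	NA
4	lrsms	Y253H	98.1
4	lrsms	E255	1.7
5	sanger	-	NA
5	lrsms	M244V	0.9
6	sanger	-	NA
6	lrsms	-	NA
7	sanger	Y253H	NA
7	lrsms	Y253H	99.8
8	sanger	-	NA
8	lrsms	-	NA
9	sanger	-	NA
9	lrsms	-	NA
10	sanger	T315I	NA
10	lrsms	T315I	99.9
11	sanger	-	NA
11	lrsms	-	NA
12	sanger	T315I	NA
12	lrsms	T315I	50.0
12	lrsms	E255V	1.9
13	sanger	-	NA
13	lrsms	-	NA
14	sanger	T315I	NA
14	sanger	E255K	NA
14	sanger	F359V	NA
14	lrsms	T315I	45.7
14	lrsms	F359I	23.9
14	lrsms	E255K	12.5
14	lrsms	H396R	12.4
14	lrsms	F359V	4.8
15	sanger	L273M	NA
15	sanger	T315I	NA
15	lrsms	L273M	58.1
15	lrsms	T315I	41.7
15	lrsms	K247R	2.8
16	sanger	T315I	NA
16	lrsms	T315I	99.8
17	sanger	-	NA
17	lrsms	-	NA
18	sanger	-	NA
18	lrsms	E450G	0.5
19	sanger	-	NA
19	lrsms	-	NA
20	sanger	-	NA
20	lrsms	-	NA
21	sanger	-	NA
21	lrsms	-	NA
22	sanger	-	NA
22	lrsms	-	NA
23	sanger	-	NA
23	lrsms	-	NA
24	sanger	F359I	NA
24	lrsms	F359I	91.3
24	lrsms	T315I	8.3
25	sanger	-	NA
25	lrsms	-	NA
26	sanger	-	NA
26	lrsms	T315I	0.6
26	lrsms	E450G	0.5
27	sanger	-	NA
27	lrsms	-	NA
28	sanger	-	NA
28	lrsms	M472I	0.8
29	sanger	F359V	NA
29	lrsms	F359V	99.9
29	lrsms	D276G	0.7
30	sanger	-	NA
30	lrsms	-	NA
31	sanger	-	NA
31	lrsms	-	NA
32	sanger	-	NA
32	lrsms	-	NA
33	sanger	L298V	NA
33	sanger	E255K	NA
33	lrsms	L298V	33.6
33	lrsms	E255K	29.6
34	sanger	-	NA
34	lrsms	-	NA
35	sanger	-	NA
35	lrsms	E450G	0.8
36	sanger	-	NA
36	lrsms	-	NA
37	sanger	-	NA
37	lrsms	-	NA
38	sanger	-	NA
38	lrsms	-	NA
39	sanger	-	NA
39	lrsms	-	NA
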