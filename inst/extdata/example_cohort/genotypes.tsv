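sample_id	position	allele	intensity	baseline
s1	73	A	12	3
s1	295	C	12	3
s1	462	C	12	3
s1	489	T	12	3
s1	1438	G	12	3
s1	1719	G	12	3
s1	2706	A	12	3
s1	3010	G	12	3
s1	3197	T	12	3
s1	3348	A	12	3
s1	3992	T	12	3
s1	4216	T	12	3
s1	4580	G	12	3
s1	5004	C	12	3
s1	5633	C	12	3
s1	6221	T	12	3
s1	6371	C	12	3
s1	6776	T	12	3
s1	7028	C	12	3
s1	8269	G	12	3
s1	8994	G	12	3
s1	9055	G	12	3
s1	9698	T	12	3
s1	10238	T	12	3
s1	10398	A	12	3
s1	10463	T	12	3
s1	10499	A	12	3
s1	11467	A	12	3
s1	11674	C	12	3
s1	11812	A	12	3
s1	12633	C	12	3
s1	12705	C	12	3
s1	13368	G	12	3
s1	14070	A	12	3
s1	14139	A	12	3
s1	14766	C	12	3
s1	15904	C	12	3
s1	16270	C	12	3
s1	16298	T	12	3
s2	73	G	12	3
s2	295	T	12	3
s2	462	T	12	3
s2	489	C	12	3
s2	1438	G	12	3
s2	1719	G	12	3
s2	2706	G	12	3
s2	3010	G	12	3
s2	3197	T	12	3
s2	3348	A	12	3
s2	3992	C	12	3
s2	4216	C	12	3
s2	4580	G	12	3
s2	5004	T	12	3
s2	5633	C	12	3
s2	6221	T	12	3
s2	6371	C	12	3
s2	6776	T	12	3
s2	7028	T	12	3
s2	8269	G	12	3
s2	8994	G	12	3
s2	9055	G	12	3
s2	9698	T	12	3
s2	10238	T	12	3
s2	10398	A	12	3
s2	10463	T	12	3
s2	10499	A	12	3
s2	11467	A	12	3
s2	11674	C	12	3
s2	11812	A	12	3
s2	12633	C	12	3
s2	12705	C	12	3
s2	13368	G	12	3
s2	14070	A	12	3
s2	14139	A	12	3
s2	14766	T	12	3
s2	15904	C	12	3
s2	16270	C	12	3
s2	16298	T	12	3
s3	73	A	12	3
s3	295	C	12	3
s3	462	C	12	3
s3	489	T	12	3
s3	1438	G	12	3
s3	1719	G	12	3
s3	2706	A	12	3
s3	3010	N	12	3
s3	3197	T	12	3
s3	3348	A	12	3
s3	3992	C	12	3
s3	4216	T	12	3
s3	4580	G	12	3
s3	5004	T	12	3
s3	5633	C	12	3
s3	6221	T	12	3
s3	6371	C	12	3
s3	6776	T	12	3
s3	7028	C	12	3
s3	8269	G	12	3
s3	8994	G	12	3
s3	9055	G	12	3
s3	9698	T	12	3
s3	10238	T	12	3
s3	10398	A	12	3
s3	10463	T	12	3
s3	10499	A	12	3
s3	11467	A	12	3
s3	11674	C	12	3
s3	11812	A	12	3
s3	12633	C	12	3
s3	12705	C	12	3
s3	13368	G	12	3
s3	14070	A	12	3
s3	14139	A	12	3
s3	14766	C	12	3
s3	15904	C	12	3
s3	16270	C	12	3
s3	16298	T	12	3
s4	73	G	12	3
s4	295	T	12	3
s4	462	T	12	3
s4	489	C	12	3
s4	1438	G	12	3
s4	1719	G	12	3
s4	2706	G	12	3
s4	3010	G	12	3
s4	3197	T	12	3
s4	3348	A	12	3
s4	3992	C	12	3
s4	4216	C	12	3
s4	4580	G	12	3
s4	5004	T	12	3
s4	5633	C	12	3
s4	6221	T	12	3
s4	6371	C	12	3
s4	6776	T	12	3
s4	7028	T	12	3
s4	8269	G	12	3
s4	8994	G	12	3
s4	9055	A	12	3
s4	9698	T	12	3
s4	10238	T	12	3
s4	10398	A	12	3
s4	10463	T	12	3
s4	10499	A	12	3
s4	11467	A	12	3
s4	11674	C	12	3
s4	11812	A	12	3
s4	12633	C	12	3
s4	12705	C	12	3
s4	13368	G	12	3
s4	14070	A	12	3
s4	14139	A	12	3
s4	14766	T	12	3
s4	15904	C	12	3
s4	16270	C	12	3
s4	16298	T	12	3
s5	73	N	12	3
s5	295	N	12	3
s5	462	N	12	3
s5	489	N	12	3
s5	1438	G	12	3
s5	1719	G	12	3
s5	2706	G	12	3
s5	3010	G	12	3
s5	3197	C	12	3
s5	3348	A	12	3
s5	3992	C	12	3
s5	4216	T	12	3
s5	4580	G	12	3
s5	5004	T	12	3
s5	5633	C	12	3
s5	6221	T	12	3
s5	6371	C	12	3
s5	6776	T	12	3
s5	7028	T	12	3
s5	8269	G	12	3
s5	8994	G	12	3
s5	9055	G	12	3
s5	9698	T	12	3
s5	10238	T	12	3
s5	10398	A	12	3
s5	10463	T	12	3
s5	10499	A	12	3
s5	11467	G	12	3
s5	11674	C	12	3
s5	11812	A	12	3
s5	12633	C	12	3
s5	12705	C	12	3
s5	13368	G	12	3
s5	14070	A	12	3
s5	14139	A	12	3
s5	14766	T	12	3
s5	15904	C	12	3
s5	16270	T	12	3
s5	16298	T	12	3
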