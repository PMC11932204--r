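# Turner 2004 length-dependent loop initiation free energies, kcal/mol, 37 C.
# size = number of unpaired nucleotides (both strands summed for internal
# loops). Internal loops of size 1 cannot occur (a two-sided loop has at least
# one unpaired nucleotide per strand); the size-1 entry duplicates size 2 so
# the table is total on sizes 1..30. Sizes beyond 30 are extrapolated
# logarithmically (Jacobson-Stockmayer) at lookup time.
size	bulge	internal
1	3.80	1.00
2	2.80	1.00
3	3.20	1.00
4	3.60	1.10
5	4.00	2.00
6	4.40	2.00
7	4.60	2.10
8	4.70	2.30
9	4.80	2.40
10	4.90	2.50
11	5.00	2.60
12	5.10	2.70
13	5.20	2.80
14	5.30	2.90
15	5.40	2.90
16	5.40	3.00
17	5.50	3.10
18	5.50	3.10
19	5.60	3.20
20	5.70	3.30
21	5.70	3.30
22	5.80	3.40
23	5.80	3.40
24	5.80	3.50
25	5.90	3.50
26	5.90	3.50
27	6.00	3.60
28	6.00	3.60
29	6.00	3.70
30	6.10	3.70
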