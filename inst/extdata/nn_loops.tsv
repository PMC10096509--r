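size	hairpin	bulge	internal
1	50.0	4.0	50.0
2	50.0	2.9	4.0
3	3.5	3.1	3.2
4	3.5	3.2	3.6
5	3.3	3.3	4.0
6	4.0	3.5	4.4
7	4.2	3.7	4.6
8	4.3	3.9	4.8
9	4.5	4.1	4.9
10	4.6	4.3	4.9
11	4.7	4.4	5.0
12	4.8	4.5	5.1
14	4.9	4.7	5.3
16	5.0	4.9	5.4
18	5.2	5.1	5.6
20	5.3	5.3	5.7
25	5.6	5.6	6.0
30	5.8	5.9	6.2
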