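participant	age	foi_hz	rmt	si
1	23	12	43	52
2	21	9	45	54
3	21	13	36	43
4	26	13	43	52
5	24	11	38	46
6	24	13	43	52
7	21	13	33	40
8	23	9	36	43
9	28	12	37	44
10	31	10	42	50
11	24	13	32	38
12	23	12	44	53
13	26	13	41	49
14	21	12	44	53
15	22	12	43	52
16	26	13	39	47
17	22	9	39	47
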