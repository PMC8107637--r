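1	M1	0	0	2	1
1	P1	0	M1	1	2
2	F2F	0	0	1	1
2	F2M	0	0	2	1
2	P2a	F2F	F2M	1	2
2	P2b	F2F	F2M	1	2
3	M3	0	0	2	1
3	P3	0	M3	1	2
4	F4F	0	0	1	1
4	P4	F4F	0	1	2
5	F5F	0	0	1	1
5	F5M	0	0	2	1
5	P5	F5F	F5M	2	2
5	S5a	F5F	F5M	1	1
5	S5b	F5F	F5M	2	1
5	S5c	F5F	F5M	1	1
6	P6	0	0	1	2
7	M7	0	0	2	1
7	P7a	0	M7	1	2
7	P7b	0	M7	2	2
8	P8	0	0	2	2
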