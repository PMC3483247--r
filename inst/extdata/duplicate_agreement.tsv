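pair	step	shared	unique
duplicate-1	S3	31	120
duplicate-2	S3	29	71
duplicate-3	S3	22	54
duplicate-4	S3	26	71
duplicate-5	S3	21	40
duplicate-6	S3	21	52
duplicate-7	S3	23	32
duplicate-8	S3	21	50
duplicate-9	S3	27	34
duplicate-10	S3	21	66
duplicate-11	S3	24	26
duplicate-12	S3	20	50
duplicate-1	S4	28	10
duplicate-2	S4	29	14
duplicate-3	S4	22	6
duplicate-4	S4	25	7
duplicate-5	S4	21	6
duplicate-6	S4	20	4
duplicate-7	S4	23	4
duplicate-8	S4	21	13
duplicate-9	S4	26	3
duplicate-10	S4	21	20
duplicate-11	S4	24	6
duplicate-12	S4	20	22
duplicate-1	S5	28	0
duplicate-2	S5	28	0
duplicate-3	S5	22	0
duplicate-4	S5	22	0
duplicate-5	S5	21	0
duplicate-6	S5	20	0
duplicate-7	S5	22	1
duplicate-8	S5	20	2
duplicate-9	S5	23	3
duplicate-10	S5	18	3
duplicate-11	S5	21	4
duplicate-12	S5	19	4
duplicate-1	ST	9	0
duplicate-2	ST	11	0
duplicate-3	ST	13	0
duplicate-4	ST	9	0
duplicate-5	ST	8	0
duplicate-6	ST	10	0
duplicate-7	ST	10	0
duplicate-8	ST	10	0
duplicate-9	ST	10	1
duplicate-10	ST	10	1
duplicate-11	ST	11	1
duplicate-12	ST	10	2
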