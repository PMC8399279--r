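residue	C	H	N	O	S	bonds_total	bonds_single	bonds_double	bonds_aromatic
A	3	7	1	2	0	12	11	1	0
C	3	7	1	2	1	13	12	1	0
D	4	7	1	4	0	15	13	2	0
E	5	9	1	4	0	18	16	2	0
F	9	11	1	2	0	23	16	1	6
G	2	5	1	2	0	9	8	1	0
H	6	9	3	2	0	20	14	1	5
I	6	13	1	2	0	21	20	1	0
K	6	14	2	2	0	23	22	1	0
L	6	13	1	2	0	21	20	1	0
M	5	11	1	2	1	19	18	1	0
N	4	8	2	3	0	16	14	2	0
P	5	9	1	2	0	17	16	1	0
Q	5	10	2	3	0	19	17	2	0
R	6	14	4	2	0	25	23	2	0
S	3	7	1	3	0	13	12	1	0
T	4	9	1	3	0	16	15	1	0
V	5	11	1	2	0	18	17	1	0
W	11	12	2	2	0	28	17	1	10
Y	9	11	1	3	0	24	17	1	6
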