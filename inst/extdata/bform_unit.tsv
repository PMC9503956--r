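resname	atom	x	y	z
DA	P	-3.1718	4.9916	-1.6306
DA	OP1	-1.7761	4.7655	-1.1769
DA	OP2	-3.9576	5.9574	-0.6086
DA	O5'	-3.1969	5.6872	-3.0844
DA	C5'	-2.3661	4.9530	-3.9796
DA	C4'	-1.3078	4.1940	-3.1989
DA	O4'	-0.5715	5.0653	-2.3299
DA	C3'	-0.2578	3.5470	-4.1122
DA	O3'	0.0018	4.3643	-5.2556
DA	C2'	0.9828	3.4836	-3.2032
DA	C1'	0.7463	4.6458	-2.2085
DA	N9	1.0804	3.9023	-0.8722
DA	C8	-0.0806	3.4948	-0.1155
DA	N7	-0.2077	2.1902	-0.3383
DA	C5	1.0339	1.6810	-0.5189
DA	C6	1.6039	0.3946	-0.5374
DA	N6	0.8541	-0.7259	-0.2456
DA	N1	2.9363	0.2940	-0.5607
DA	C2	3.6891	1.3592	-0.8027
DA	N3	3.1794	2.5652	-0.9362
DA	C4	1.8066	2.7184	-0.9995
DC	P	-3.1718	4.9916	-1.6306
DC	OP1	-1.7761	4.7655	-1.1769
DC	OP2	-3.9576	5.9574	-0.6086
DC	O5'	-3.1969	5.6872	-3.0844
DC	C5'	-2.3661	4.9530	-3.9796
DC	C4'	-1.3078	4.1940	-3.1989
DC	O4'	-0.5715	5.0653	-2.3299
DC	C3'	-0.2578	3.5470	-4.1122
DC	O3'	0.0018	4.3643	-5.2556
DC	C2'	0.9828	3.4836	-3.2032
DC	C1'	0.7463	4.6458	-2.2085
DC	N1	0.8968	4.1279	-0.7867
DC	C2	0.4901	2.8204	-0.7424
DC	O2	-0.6804	2.6292	-1.0869
DC	N3	1.3494	1.8282	-0.7569
DC	C4	2.6547	2.0561	-0.6391
DC	N4	3.4997	0.9812	-0.4480
DC	C5	3.1202	3.3830	-0.5557
DC	C6	2.2003	4.3670	-0.3154
DG	P	-3.1718	4.9916	-1.6306
DG	OP1	-1.7761	4.7655	-1.1769
DG	OP2	-3.9576	5.9574	-0.6086
DG	O5'	-3.1969	5.6872	-3.0844
DG	C5'	-2.3661	4.9530	-3.9796
DG	C4'	-1.3078	4.1940	-3.1989
DG	O4'	-0.5715	5.0653	-2.3299
DG	C3'	-0.2578	3.5470	-4.1122
DG	O3'	0.0018	4.3643	-5.2556
DG	C2'	0.9828	3.4836	-3.2032
DG	C1'	0.7463	4.6458	-2.2085
DG	N9	1.1751	4.0868	-0.8634
DG	C8	0.0101	3.7905	0.0304
DG	N7	-0.2186	2.5035	-0.2538
DG	C5	0.9824	1.9018	-0.4442
DG	C6	1.4457	0.5632	-0.4696
DG	O6	0.6894	-0.3617	-0.2328
DG	N1	2.7786	0.3455	-0.5849
DG	C2	3.6423	1.3957	-0.6866
DG	N2	4.9928	1.1490	-0.7202
DG	N3	3.2133	2.6366	-0.7595
DG	C4	1.8669	2.8986	-0.7697
DT	P	-3.1718	4.9916	-1.6306
DT	OP1	-1.7761	4.7655	-1.1769
DT	OP2	-3.9576	5.9574	-0.6086
DT	O5'	-3.1969	5.6872	-3.0844
DT	C5'	-2.3661	4.9530	-3.9796
DT	C4'	-1.3078	4.1940	-3.1989
DT	O4'	-0.5715	5.0653	-2.3299
DT	C3'	-0.2578	3.5470	-4.1122
DT	O3'	0.0018	4.3643	-5.2556
DT	C2'	0.9828	3.4836	-3.2032
DT	C1'	0.7463	4.6458	-2.2085
DT	N1	0.4744	4.0796	-0.8007
DT	C2	0.2753	2.6810	-0.7662
DT	O2	-0.6952	2.2071	-1.4085
DT	N3	1.4371	1.9526	-0.4962
DT	C4	2.7275	2.4789	-0.3566
DT	O4	3.6747	1.7597	-0.0538
DT	C5	2.7868	3.9643	-0.2312
DT	C7	4.1455	4.5884	-0.1394
DT	C6	1.5867	4.6516	-0.2267
A	P	-3.1718	4.9916	-1.6306
A	OP1	-1.7761	4.7655	-1.1769
A	OP2	-3.9576	5.9574	-0.6086
A	O5'	-3.1969	5.6872	-3.0844
A	C5'	-2.3661	4.9530	-3.9796
A	C4'	-1.3078	4.1940	-3.1989
A	O4'	-0.5715	5.0653	-2.3299
A	C3'	-0.2578	3.5470	-4.1122
A	O3'	0.0018	4.3643	-5.2556
A	C2'	0.9828	3.4836	-3.2032
A	C1'	0.7463	4.6458	-2.2085
A	O2'	2.0688	3.8049	-4.1605
A	N9	1.0804	3.9023	-0.8722
A	C8	-0.0806	3.4948	-0.1155
A	N7	-0.2077	2.1902	-0.3383
A	C5	1.0339	1.6810	-0.5189
A	C6	1.6039	0.3946	-0.5374
A	N6	0.8541	-0.7259	-0.2456
A	N1	2.9363	0.2940	-0.5607
A	C2	3.6891	1.3592	-0.8027
A	N3	3.1794	2.5652	-0.9362
A	C4	1.8066	2.7184	-0.9995
C	P	-3.1718	4.9916	-1.6306
C	OP1	-1.7761	4.7655	-1.1769
C	OP2	-3.9576	5.9574	-0.6086
C	O5'	-3.1969	5.6872	-3.0844
C	C5'	-2.3661	4.9530	-3.9796
C	C4'	-1.3078	4.1940	-3.1989
C	O4'	-0.5715	5.0653	-2.3299
C	C3'	-0.2578	3.5470	-4.1122
C	O3'	0.0018	4.3643	-5.2556
C	C2'	0.9828	3.4836	-3.2032
C	C1'	0.7463	4.6458	-2.2085
C	O2'	2.0688	3.8049	-4.1605
C	N1	0.8968	4.1279	-0.7867
C	C2	0.4901	2.8204	-0.7424
C	O2	-0.6804	2.6292	-1.0869
C	N3	1.3494	1.8282	-0.7569
C	C4	2.6547	2.0561	-0.6391
C	N4	3.4997	0.9812	-0.4480
C	C5	3.1202	3.3830	-0.5557
C	C6	2.2003	4.3670	-0.3154
G	P	-3.1718	4.9916	-1.6306
G	OP1	-1.7761	4.7655	-1.1769
G	OP2	-3.9576	5.9574	-0.6086
G	O5'	-3.1969	5.6872	-3.0844
G	C5'	-2.3661	4.9530	-3.9796
G	C4'	-1.3078	4.1940	-3.1989
G	O4'	-0.5715	5.0653	-2.3299
G	C3'	-0.2578	3.5470	-4.1122
G	O3'	0.0018	4.3643	-5.2556
G	C2'	0.9828	3.4836	-3.2032
G	C1'	0.7463	4.6458	-2.2085
G	O2'	2.0688	3.8049	-4.1605
G	N9	1.1751	4.0868	-0.8634
G	C8	0.0101	3.7905	0.0304
G	N7	-0.2186	2.5035	-0.2538
G	C5	0.9824	1.9018	-0.4442
G	C6	1.4457	0.5632	-0.4696
G	O6	0.6894	-0.3617	-0.2328
G	N1	2.7786	0.3455	-0.5849
G	C2	3.6423	1.3957	-0.6866
G	N2	4.9928	1.1490	-0.7202
G	N3	3.2133	2.6366	-0.7595
G	C4	1.8669	2.8986	-0.7697
U	P	-3.1718	4.9916	-1.6306
U	OP1	-1.7761	4.7655	-1.1769
U	OP2	-3.9576	5.9574	-0.6086
U	O5'	-3.1969	5.6872	-3.0844
U	C5'	-2.3661	4.9530	-3.9796
U	C4'	-1.3078	4.1940	-3.1989
U	O4'	-0.5715	5.0653	-2.3299
U	C3'	-0.2578	3.5470	-4.1122
U	O3'	0.0018	4.3643	-5.2556
U	C2'	0.9828	3.4836	-3.2032
U	C1'	0.7463	4.6458	-2.2085
U	O2'	2.0688	3.8049	-4.1605
U	N1	0.4744	4.0796	-0.8007
U	C2	0.2753	2.6810	-0.7662
U	O2	-0.6952	2.2071	-1.4085
U	N3	1.4371	1.9526	-0.4962
U	C4	2.7275	2.4789	-0.3566
U	O4	3.6747	1.7597	-0.0538
U	C5	2.7868	3.9643	-0.2312
U	C6	1.5867	4.6516	-0.2267
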