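snp_id	position	a1	mode	or_meta	or_trait1	or_trait2	p_meta	p_trait1	p_trait2	pp_h4
rs7960611	12:10230416	G	aligned	1.14 (1.09-1.19)	1.11 (1.05-1.17)	1.17 (1.10-1.25)	8.02e-09	2.76e-04	3.31e-07	0.954
rs6869688	5:158883027	G	aligned	0.92 (0.90-0.95)	0.90 (0.87-0.94)	0.94 (0.91-0.98)	4.57e-08	1.79e-08	1.96e-03	0.815
rs10460393	2:198548306	T	aligned	1.09 (1.06-1.13)	1.11 (1.07-1.14)	1.08 (1.04-1.13)	1.07e-09	2.11e-08	6.48e-05	0.807
rs2431697	5:159879978	C	aligned	0.90 (0.87-0.92)	0.84 (0.81-0.87)	0.94 (0.91-0.98)	8.51e-14	2.12e-20	2.42e-03	0.805
rs4792891	17:43973498	G	aligned	0.90 (0.88-0.93)	0.92 (0.89-0.96)	0.90 (0.86-0.93)	6.82e-10	1.40e-05	3.37e-08	0.563
rs5022165	1:67788352	A	aligned	1.12 (1.08-1.16)	1.17 (1.12-1.23)	1.07 (1.02-1.13)	9.10e-09	1.82e-12	8.52e-03	0.230
rs3024897	2:191896564	C	aligned	0.87 (0.83-0.91)	0.82 (0.77-0.87)	0.91 (0.86-0.97)	1.06e-08	1.17e-10	5.41e-03	0.146
rs35605052	3:45916547	T	aligned	1.16 (1.12-1.21)	1.08 (1.03-1.13)	1.25 (1.18-1.32)	2.14e-13	6.95e-04	1.02e-14	0.0603
rs7970893	12:113390679	T	aligned	0.92 (0.90-0.95)	0.94 (0.91-0.98)	0.90 (0.87-0.94)	2.10e-08	2.26e-03	1.28e-07	0.0000
rs11085727	19:10466123	T	opposing	1.21 (1.17-1.25)	0.80 (0.77-0.84)	1.19 (1.14-1.23)	2.09e-31	6.92e-27	2.33e-18	0.993
rs74956615	19:10427721	A	opposing	1.51 (1.39-1.63)	0.58 (0.53-0.65)	1.40 (1.29-1.53)	2.19e-25	2.75e-24	3.04e-14	0.991
rs1174683	1:183650428	G	opposing	1.16 (1.11-1.22)	0.82 (0.77-0.87)	1.12 (1.05-1.18)	2.37e-09	3.98e-10	1.50e-04	0.601
rs5778759	1:173328868	C	opposing	1.13 (1.09-1.16)	0.83 (0.80-0.86)	1.06 (1.01-1.11)	3.32e-13	1.98e-22	9.66e-03	0.368
rs17445836	16:86017663	A	opposing	1.14 (1.09-1.19)	0.83 (0.79-0.87)	1.07 (1.02-1.13)	5.14e-10	3.68e-16	7.11e-03	0.357
rs61811916	1:155045004	C	opposing	1.14 (1.09-1.19)	1.11 (1.05-1.17)	0.85 (0.80-0.91)	4.11e-08	4.59e-04	4.86e-07	0.0801
rs76073397	16:11386452	C	opposing	1.14 (1.09-1.19)	0.90 (0.84-0.95)	1.15 (1.09-1.22)	3.21e-08	5.14e-04	9.67e-07	0.0118
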