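# Hand-transcribed per-tumor sequencing summary (16 tumors): TMB in mutations
# per megabase plus nonsynonymous variants per gene column, ';'-separated,
# somatic unless the column is suffixed _germline.
# The publisher's flattened layout loses column boundaries; this transcription
# was solved against the printed per-gene footer counts (APC 8/16, AMER1 7/16,
# KRAS 9/16, BRAF 5/16, TP53 6/16, ARID1A 10/16, ALK 4/16, MLH1 somatic 2/16,
# PMS2 somatic 2/16, MLH1 germline 1/16), the running-text per-sample variant
# confirmations, per-row token order, and protein lengths.
# Uncertain cells: the gene of CRC_3 p.M73W_fs (TP53 here; recurrent under TP53
# in CRC_9/CRC_13) vs CRC_2 p.A282V (ARID1A here); both satisfy all counts.
sample	tmb	APC	AMER1	KRAS	BRAF	TP53	ARID1A	ALK	MLH1	MSH2	MSH6	PMS2	MLH1_germline	MSH2_germline	MSH6_germline	PMS2_germline
CRC_1	40.71		p.F173L_fs	p.Q61R			p.P1328R_fs;p.H2020N									
CRC_2	42.66		p.R630L	p.G12D			p.A282V;p.G859E	p.R28S				p.E745K				
CRC_3	50.36					p.M73W_fs	p.Q423K;p.S748N	p.G902R								
CRC_4	19.71	p.A2120T	p.Q978*	p.G12S;p.G13D	p.R356Q				p.S404Y							
CRC_5	23.72						p.G875R						p.R516W			
CRC_6	31.03	p.R2759H			p.P399L_fs	p.R175H			p.R497G_fs			p.T680M				
CRC_7	13.38	p.R1450*		p.A59T				p.A273P_fs								
CRC_8	15.52	p.G721*;p.T1556N_fs		p.G12D			p.G771S;p.P1569L_fs									
CRC_9	41.38		p.A36V;p.K238N;p.K260N_fs;p.A622P_fs	p.G13D;p.R68W	p.P399L_fs	p.M73W_fs;p.A119V;p.R175H;p.R337H	p.F2142S_fs									
CRC_10	47.47	p.L204I;p.R2721H	p.F173L_fs	p.G12D;p.A146T	p.P399L_fs	p.P142L	p.L2240F;p.A2238S	p.Q500R								
CRC_11	19.74			p.A146T												
CRC_12	32.17	p.A1296T;p.A1755V;p.N1792M_fs	p.F173L_fs	p.G12D			p.R1278*;p.D1851T_fs									
CRC_13	25.85	p.N627L_fs	p.F173L_fs		p.R667Q	p.M73W_fs										
CRC_14	30.98	p.Y796C;p.R1687Q				p.R273*	p.P1569L_fs									
CRC_15	17.66															
CRC_16	22.98						p.P1408Q_fs									
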