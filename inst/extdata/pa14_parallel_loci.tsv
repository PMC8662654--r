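locus	total_cases	ns	s	indel	biofilm_cases	planktonic_cases	B1	B2	B3	P1	P2	P3	functional_class
argJ	3	3	0	0	2	1		13.5	10.5			11.4	Arginine biosynthesis
soxA	3	2	1	0	1	2			10.6		14.7	11.4	Carbon compound catabolism
aer2	5	3	2	0	3	2		9.6	10.9	10.2		14.2	Chemotaxis
bdlA	3	3	0	0	3	0	14.4	14.7	13.5				Chemotaxis
cobG	3	2	0	1	1	2		61.8			13.6	13.1	Cofactor biosynthesis
mutS	3	3	0	0	2	1	100	100				52.6	DNA replication
napF	3	3	0	0	2	1	13.8		10.9			10.7	Energy metabolism
nqrE	3	3	0	0	1	2		11.7			10.4	11.2	Energy metabolism
nuoG	3	3	0	0	1	2	12.9			12.1	13.9		Energy metabolism
PA14_53110	7	7	0	0	2	5		14.8	12.8	12.9	14.4	12.1	Putative enzymes
pslI	7	7	0	0	3	4	16.7	16.4	14.6	16	14.7		Putative enzymes
algF	3	3	0	0	2	1	13.1			10.6			Secreted factors
fha1	4	4	0	0	3	1	27.6		25.1	35.8			Secreted factors
rpoB	4	4	0	0	4	0	100	66	100				Transcription
PA14_13150	3	3	0	0	3	0	46.3	17.8	100				Transcriptional regulators
PA14_18200	6	6	0	0	5	1	22.3	22.1		12.8			Transcriptional regulators
PA14_51840	3	3	0	0	0	3					12	16.6	Transcriptional regulators
PA14_58510	5	3	2	0	4	1	23	15.7		15.5			Transcriptional regulators
PA14_71750	3	3	0	0	3	0	93.9	89.7					Transcriptional regulators
dsbA2	4	2	2	0	3	1	17.1	11.4	20.8			10.5	Translation
rluB	10	8	2	0	4	6	10.8	17.7			14.7	13.2	Translation
nosD	5	4	1	0	1	4	14.1				15.3	12.9	Transporter
PA14_09300	3	3	0	0	2	1	16		15.2	18.6			Transporter
PA14_22650	7	7	0	0	3	4	43.2	24		40	28	37.8	Transporter
PA14_45060	6	6	0	0	2	4	24.4	19.1		19.5	14.1	13.6	Transporter
PA14_46110	7	7	0	0	1	6			15.5	13.7	13.6	10.7	Transporter
PA14_47900	3	3	0	0	0	3						19.9	Transporter
pchF	3	3	0	0	3	0	18.4		19				Transporter
pitA	4	2	0	2	2	3		91.1		100	75.8	100	Transporter
pntB	5	3	2	0	1	4	11.3				13.9	15.6	Transporter
PA14_10770	3	2	1	0	1	2		100		12.2		26.3	Two-component regulatory systems
PA14_32300	3	3	0	0	2	1	17.1					15.3	Two-component regulatory systems
gacS	3	3	0	0	3	0	85.2	92.2					Two-component regulatory systems
PA14_01160	3	3	0	0	1	2	14.3				13.8		Unknown
PA14_20510	6	6	0	0	3	3	9.6	11.5		11	11.9	11.1	Unknown
PA14_31070	10	5	5	0	4	6	19.3	16.9		16.2	16.9		Unknown
PA14_32830	6	6	0	0	2	4		13.8	12.7	12.1	13.5	12.1	Unknown
PA14_54810	3	3	0	0	3	0	11.7		7.5				Unknown
PA14_58070	6	6	0	0	5	1	13.6	17.5	12.9		20.8		Unknown
PA14_69010	5	5	0	0	3	2	20.1	12.2	13	12.5		12.4	Unknown
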