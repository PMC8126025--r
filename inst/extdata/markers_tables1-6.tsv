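# Curated subcellular membrane marker proteins with their compartment and
# the source marker table (1 = overview panel, 2 = tonoplast, 3 = secretory
# pathway, 4 = chloroplast envelope/thylakoid, 5 = mitochondria, 6 = plasma
# membrane). Compartment labels: TP tonoplast, ER endoplasmic reticulum,
# GA Golgi (incl. ER-Golgi exchange), TGN trans-Golgi network,
# Chl-envelope chloroplast envelope, TLK thylakoid, MT mitochondria,
# PM plasma membrane. A gene may recur across source tables but always
# under a single compartment.
gene	compartment	source_table
VHA-a3	TP	1
TIP1-1	TP	1
KCR1	ER	1
CYTB5-B	ER	1
GAUT1	GA	1
GAUT9	GA	1
TIC110	Chl-envelope	1
LHCB1.3	TLK	1
VDAC2	MT	1
PHB3	MT	1
AHA2	PM	1
mipA	PM	1
VHA-A	TP	2
VHA-B2	TP	2
VHA-C	TP	2
VHA-D	TP	2
VHA-E3	TP	2
VHA-F	TP	2
VHA-G1	TP	2
VHA-H	TP	2
VHA-a3	TP	2
VHA-c2	TP	2
VHA-d2	TP	2
AVP1	TP	2
TIP2-1	TP	2
TIP1-1	TP	2
TPC1	TP	2
CLC-B	TP	2
CLC-C	TP	2
CRT1	ER	3
STL2P	ER	3
OST1B	ER	3
At2g21160	ER	3
BIP2	ER	3
ARF1	GA	3
At1g62020	GA	3
At4g31480	GA	3
At1g52360	GA	3
At4g34450	GA	3
At3g07100	GA	3
APY2	GA	3
GAUT1	GA	3
GAUT9	GA	3
At1g04430	GA	3
At1g60070	TGN	3
CHC1	TGN	3
TIC55	Chl-envelope	4
TIC110	Chl-envelope	4
TOC34	Chl-envelope	4
At4g02530	TLK	4
ATPC1	TLK	4
ATPD	TLK	4
LHCB1.3	TLK	4
LHCA1	TLK	4
PSAD2	TLK	4
PSAF	TLK	4
PSAH2	TLK	4
PSAL	TLK	4
PSAK	TLK	4
HCF136	TLK	4
PSBR	TLK	4
VDAC1	MT	5
VDAC2	MT	5
VDAC4	MT	5
TOM9-2	MT	5
PHB2	MT	5
PHB3	MT	5
At5g08680	MT	5
UCR1-1	MT	5
COX5B-2	MT	5
MPPbeta	MT	5
BOU	MT	5
MPT3	MT	5
DTC	MT	5
AHA2	PM	6
AHA4	PM	6
AHA5	PM	6
mipA	PM	6
mipD	PM	6
mipH	PM	6
PIP2-5	PM	6
PIP2-8	PM	6
ERD4	PM	6
SUC2	PM	6
PLT5	PM	6
FLA2	PM	6
FLA6	PM	6
At4g27520	PM	6
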