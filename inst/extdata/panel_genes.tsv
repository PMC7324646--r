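gene	coverage	chrom
BCOR	complete_exons	chrX
BCORL1	complete_exons	chrX
CDKN2A	complete_exons	chr9
CEBPA	complete_exons	chr19
CUX1	complete_exons	chr7
DNMT3A	complete_exons	chr2
ETV6	complete_exons	chr12
EZH2	complete_exons	chr7
KDM6A	complete_exons	chrX
IKZF1	complete_exons	chr7
PHF6	complete_exons	chrX
RAD21	complete_exons	chr8
RUNX1	complete_exons	chr21
STAG2	complete_exons	chrX
ZRSR2	complete_exons	chrX
ABL1	hotspots	chr9
ASXL1	hotspots	chr20
ATRX	hotspots	chrX
BRAF	hotspots	chr7
CALR	hotspots	chr19
CBL	hotspots	chr11
CBLB	hotspots	chr3
CBLC	hotspots	chr19
CSF3R	hotspots	chr1
FBXW7	hotspots	chr4
FLT3	hotspots	chr13
GATA1	hotspots	chrX
GATA2	hotspots	chr3
GNAS	hotspots	chr20
HRAS	hotspots	chr11
IDH1	hotspots	chr2
IDH2	hotspots	chr15
JAK2	hotspots	chr9
JAK3	hotspots	chr19
KIT	hotspots	chr4
KRAS	hotspots	chr12
KMT2A	hotspots	chr11
MPL	hotspots	chr1
MYD88	hotspots	chr3
NOTCH1	hotspots	chr9
NPM1	hotspots	chr5
NRAS	hotspots	chr1
PDGFRA	hotspots	chr4
PTEN	hotspots	chr10
PTPN11	hotspots	chr12
SETBP1	hotspots	chr18
SF3B1	hotspots	chr2
SMC1A	hotspots	chrX
SMC3	hotspots	chr10
SRSF2	hotspots	chr17
TET2	hotspots	chr4
TP53	hotspots	chr17
U2AF1	hotspots	chr21
WT1	hotspots	chr11
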