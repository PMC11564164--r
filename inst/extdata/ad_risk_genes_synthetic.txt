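# Synthetic stand-in for a 52-symbol literature AD risk-gene list.
# The first 12 symbols are the consistently associated genes; the rest are
# established AD GWAS locus symbols assembled from the literature.
ABCA7
SORCS1
SORL1
PILRA
PFDN1
PLXNA4
TRIP4
CD2AP
CD33
PLCG2
APOE
ECHDC3
APP
PSEN1
PSEN2
BIN1
CLU
CR1
PICALM
MS4A6A
ABCA1
TREM2
EPHA1
INPP5D
HLA-DRB1
PTK2B
FERMT2
SLC24A4
CASS4
ZCWPW1
NME8
CELF1
MEF2C
DSG2
ADAM10
ACE
ADAMTS1
IQCK
WWOX
SPI1
APH1B
SCIMP
ABI3
KAT8
CLNK
TSPAN14
HESX1
USP6NL
TREML2
SPPL2A
IL34
PLD3
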