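# 24-gene medulloblastoma subgroup classifier panel.
# On U133A-style arrays the last four genes are typically absent and
# classification proceeds on the remaining twenty.
LEF1
RUNX2
DCX
MAB21L1
PTCH1
PDLIM3
NEUROG1
DLL3
PDGFA
FOXG1B
GRM1
VAMP4
CDKN1C
SERPINF1
NRL
CRX
NMNAT2
SMARCD3
GABRA5
DCC
OTX2
LEMD1
PTPN5
ZNF179
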