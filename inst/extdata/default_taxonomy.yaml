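IDH:
- wildtype
- IDH1 G395A
- IDH1 C394T
- IDH1 C394G
- IDH1 C394A
- IDH1 G395T
- IDH2 G515A
- IDH2 A514T
- IDH2 A514G
- IDH2 G515T
- IDH1 G394T
MGMT:
- unmethylated
- 0-5% methylation
- 5-10% methylation
- 10-25% methylation
- '>25% methylation'
EGFR:
- no amplification
- low amplification
- moderate amplification
- high amplification
1p/19q:
- no codeletion
- 1p/19q codeletion
- 19q deletion
Histone:
- wildtype
- Hist K27M
- Hist G34R
TERT:
- wildtype
- TERT C228T
- TERT C250T
ATRX:
- retained
- loss of expression
BRAF:
- wildtype
- BRAF 1799 T>A
- BRAF frameshift
- BRAF Exon 16-9
- BRAF Exon 15-9
- BRAF Exon 16-11
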