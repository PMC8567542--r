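codon	frequency
AAA	1437
AAC	1853
AAG	91
AAT	966
ACA	936
ACC	1996
ACG	1798
ACT	1792
AGA	1844
AGC	898
AGG	1985
AGT	1062
ATA	949
ATC	181
ATG	714
ATT	181
CAA	1516
CAC	1253
CAG	519
CAT	1382
CCA	955
CCC	1489
CCG	1965
CCT	718
CGA	714
CGC	1957
CGG	1670
CGT	1907
CTA	1440
CTC	1641
CTG	560
CTT	938
GAA	1751
GAC	1653
GAG	460
GAT	1274
GCA	993
GCC	383
GCG	1791
GCT	852
GGA	285
GGC	327
GGG	1306
GGT	265
GTA	1181
GTC	1997
GTG	1119
GTT	469
TAA	1449
TAC	263
TAG	1578
TAT	80
TCA	962
TCC	1711
TCG	1707
TCT	498
TGA	1810
TGC	1868
TGG	1633
TGT	1104
TTA	1848
TTC	180
TTG	241
TTT	1672
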