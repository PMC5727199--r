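codon	frequency
AAA	0.00751
AAC	0.014851
AAG	0.016955
AAT	0.036149
ACA	0.01292
ACC	0.0158
ACG	0.006433
ACT	0.016543
AGA	0.014316
AGC	0.005551
AGG	0.013993
AGT	0.003953
ATA	0.033415
ATC	0.017075
ATG	0.009502
ATT	0.030902
CAA	0.005176
CAC	0.006721
CAG	0.013387
CAT	0.01091
CCA	0.016529
CCC	0.018605
CCG	0.008064
CCT	0.008342
CGA	0.042169
CGC	0.007022
CGG	0.034992
CGT	0.012149
CTA	0.027967
CTC	0.006905
CTG	0.010576
CTT	0.009739
GAA	0.033514
GAC	0.008261
GAG	0.017896
GAT	0.015337
GCA	0.017637
GCC	0.008656
GCG	0.012331
GCT	0.013983
GGA	0.007759
GGC	0.008571
GGG	0.03449
GGT	0.005529
GTA	0.06397
GTC	0.004166
GTG	0.017486
GTT	0.006286
TAA	0.013086
TAC	0.027572
TAG	0.019452
TAT	0.003701
TCA	0.004105
TCC	0.020164
TCG	0.017686
TCT	0.011349
TGA	0.013309
TGC	0.009792
TGG	0.009489
TGT	0.016657
TTA	0.04152
TTC	0.009819
TTG	0.005815
TTT	0.005489
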