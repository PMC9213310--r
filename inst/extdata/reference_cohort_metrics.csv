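caseId,region,lesionType,mad,md,dsc,rmsd
P1,bone,mixed,102,34,0.81,2.70
P2,bone,mixed,146,23,0.86,2.54
P3,bone,osteoblastic,132,-26,0.74,1.74
P4,bone,osteolytic,96,-47,0.85,1.38
P5,bone,osteolytic,77,29,0.88,1.67
P6,bone,osteoblastic,154,119,0.90,1.90
P7,bone,osteoblastic,136,-98,0.89,2.11
P8,bone,osteolytic,109,87,0.9,1.76
P9,bone,osteoblastic,95,7,0.85,2.65
P1,lesion,mixed,94,-64,0.56,4.93
P2,lesion,mixed,143,-55,0.86,2.86
P3,lesion,osteoblastic,166,101,0.82,2.08
P4,lesion,osteolytic,188,100,0.74,1.42
P5,lesion,osteolytic,27,12,0.77,0.75
P6,lesion,osteoblastic,235,-229,0.96,0.89
P7,lesion,osteoblastic,81,29,0.99,2.08
P8,lesion,osteolytic,108,-51,0.60,3.87
P9,lesion,osteoblastic,149,-123,0.49,7.30
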