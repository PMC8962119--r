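marker,primer_name,direction,sequence_5to3
bcLK033,bcLK033-F,forward,GGAAATGTAGAGATGAGCAATAA
bcLK033,bcLK033-R,reverse,AGGTGCGGTAGTACAAAGTGA
bcLK224,bcLK224-F,forward,GGAGAGGCCACTACTATTATTAC
bcLK224,bcLK224-R,reverse,ATGCGTTCCTTCATTCCTCT
bcLK235,bcLK235-F,forward,TTCACTTGTGATCCTAGAGTTAGA
bcLK235,bcLK235-R,reverse,AACCCCTAACCATATAATATCCA
bcLK241,bcLK241-F,forward,TGAGGTTAGGAGCATCTCGT
bcLK241,bcLK241-R,reverse,GTCCTTCATCGCCTCTTCTT
LK4146,LK4146-F,forward,CAACATGTTTCTCCTACCACCA
LK4146,LK4146-R,reverse,TCAGACATTCCCAAACATGC
LK4170,LK4170-F,forward,TTTTCCAAAGCCAAAATTCTACA
LK4170,LK4170-R,reverse,TATGAGCCCGACCCTATTTG
LK4178,LK4178-F,forward,TCCACCTTAGCACTCCCACT
LK4178,LK4178-R,reverse,GGGGCCTTTATAGGTTGGTT
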