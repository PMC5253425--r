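ClusterIndex ClusterProbability OffspringID FatherID MotherID
1 1.0 O00001 S1 D1
1 1.0 O00002 S1 D1
1 1.0 O00003 S1 D1
2 1.0 O00004 S2 D2
2 1.0 O00005 S2 D2
3 1.0 O00006 S2 D3
4 1.0 O00007 S3 D4
5 1.0 O00008 S4 D5
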