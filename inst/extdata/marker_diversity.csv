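marker,n_species,n_accessions,matrix_length,inter_mean_distance,intra_mean_distance,overall_mean_distance,inter_mean_diversity,intra_mean_diversity,overall_mean_diversity,coefficient
5.8S,121,912,182,0.0922,0.0019,0.0877,0.0859,0.0019,0.0877,0.9789
matK,113,785,1234,0.0771,0.0034,0.0765,0.0731,0.0034,0.0765,0.9558
trnL-F,109,498,690,0.1333,0.0070,0.1297,0.1228,0.0070,0.1297,0.9462
trnH-psbA,109,487,1039,0.0515,0.0038,0.0480,0.0442,0.0038,0.0480,0.9205
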