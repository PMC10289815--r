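cultivar,trait,model,gpi,rank
Coratina,phenols,BPNN,-0.15014,2
Coratina,phenols,PCA_BPNN,0.17129,1
Coratina,phenols,SPCA_BPNN,-0.17755,3
Coratina,oil,BPNN,-0.1025,3
Coratina,oil,PCA_BPNN,0.21589,2
Coratina,oil,SPCA_BPNN,0.37732,1
Frantoio,phenols,BPNN,-0.41955,3
Frantoio,phenols,PCA_BPNN,0.03186,2
Frantoio,phenols,SPCA_BPNN,0.43254,1
Frantoio,oil,BPNN,-0.51611,3
Frantoio,oil,PCA_BPNN,-0.34027,2
Frantoio,oil,SPCA_BPNN,0.17350,1
Leccino,phenols,BPNN,0.41724,1
Leccino,phenols,PCA_BPNN,0.10131,3
Leccino,phenols,SPCA_BPNN,0.17279,2
Leccino,oil,BPNN,-0.05665,1
Leccino,oil,PCA_BPNN,-0.16239,2
Leccino,oil,SPCA_BPNN,-0.62195,3
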