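comparison,drug,numerator_label,numerator_ic50_nM,denominator_label,denominator_ic50_nM,reported_fold
resistance,docetaxel,22Rv1DOC8,54.6,22Rv1,1.3,42.0
resistance,docetaxel,DU-145DOC10,9.5,DU-145,2.9,3.3
sensitization,docetaxel,DU-145DOC10,9.5,DU-145DOC10 + 10 uM ritonavir,2.8,3.4
resistance,cabazitaxel,DU-145DOC10,1.5,DU-145,0.6,2.5
resistance,cabazitaxel,22Rv1DOC8,9.5,22Rv1,0.7,13.6
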