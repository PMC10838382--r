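compound,inhibitor,conc_uM,inh_conc_uM,time_min,papp_ab_e6,papp_ba_e6,reported_er
docetaxel,none,10,0,60,0.66,21.03,31.80
docetaxel,valspodar,10,10,60,5.20,5.39,1.04
docetaxel,ritonavir,10,50,60,5.33,6.62,1.24
docetaxel,none,5,0,60,0.29,20.27,69.46
docetaxel,valspodar,5,10,60,1.61,4.02,2.49
docetaxel,ritonavir,5,50,60,2.87,5.74,2.00
docetaxel,none,10,0,120,0.91,29.62,32.66
docetaxel,valspodar,10,10,120,8.91,9.51,1.07
docetaxel,ritonavir,10,50,120,10.76,11.59,1.08
docetaxel,none,5,0,120,0.81,35.40,43.85
docetaxel,valspodar,5,10,120,8.06,8.58,1.06
docetaxel,ritonavir,5,50,120,7.41,11.83,1.60
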