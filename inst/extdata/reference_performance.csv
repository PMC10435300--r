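score,outcome,auc,cutoff,sensitivity,specificity,ppv,npv
smart,died_7d,0.789,2,90,59,15.1,98.6
smart,died_30d,0.786,2,84.9,61.5,25.1,96.4
smart,icu_admit,0.758,2,77.6,68.8,50.3,88.3
qsofa,died_7d,0.699,2,56.7,77.4,16.8,95.7
qsofa,died_30d,0.681,1,83,45.7,18.9,94.6
qsofa,icu_admit,0.717,1,84.5,52.6,42.1,89.3
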