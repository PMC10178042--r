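table,model,class,accuracy,precision,sensitivity,f1
classical,ELM,All,79.50,80.29,79.50,0.7962
classical,ELM,None,75.00,78.95,75.00,0.7692
classical,ELM,Acetamiprid,82.50,89.19,82.50,0.8571
classical,ELM,Malathion,82.50,73.33,82.50,0.7765
classical,ELM,Difenoconazole,82.50,71.74,82.50,0.7674
classical,ELM,Beta-cypermethrin,75.00,88.24,75.00,0.8108
classical,SVM,All,77.50,78.03,77.50,0.7760
classical,SVM,None,75.00,78.95,75.00,0.7692
classical,SVM,Acetamiprid,77.50,86.11,77.50,0.8158
classical,SVM,Malathion,75.00,78.95,75.00,0.7692
classical,SVM,Difenoconazole,80.00,68.09,80.00,0.7356
classical,SVM,Beta-cypermethrin,80.00,78.05,80.00,0.7901
classical,PLS-DA,All,75.50,76.42,75.50,0.7555
classical,PLS-DA,None,75.00,76.92,75.00,0.7595
classical,PLS-DA,Acetamiprid,67.50,87.10,67.50,0.7606
classical,PLS-DA,Malathion,82.50,71.74,82.50,0.7674
classical,PLS-DA,Difenoconazole,77.50,67.39,77.50,0.7209
classical,PLS-DA,Beta-cypermethrin,75.00,78.95,75.00,0.7692
preprocessing,NM-ELM,All,82.00,82.07,82.00,0.8201
preprocessing,NM-ELM,None,85.00,79.07,85.00,0.8193
preprocessing,NM-ELM,Acetamiprid,90.00,92.31,90.00,0.9114
preprocessing,NM-ELM,Malathion,80.00,82.05,80.00,0.8101
preprocessing,NM-ELM,Difenoconazole,80.00,80.00,80.00,0.8000
preprocessing,NM-ELM,Beta-cypermethrin,75.00,76.92,75.00,0.7595
preprocessing,MSC-ELM,All,80.50,80.87,80.50,0.8062
preprocessing,MSC-ELM,None,82.50,84.62,82.50,0.8354
preprocessing,MSC-ELM,Acetamiprid,85.00,91.89,85.00,0.8831
preprocessing,MSC-ELM,Malathion,82.50,78.57,82.50,0.8049
preprocessing,MSC-ELM,Difenoconazole,75.00,69.77,75.00,0.7229
preprocessing,MSC-ELM,Beta-cypermethrin,77.50,79.49,77.50,0.7848
preprocessing,SNV-ELM,All,80.00,80.08,80.00,0.8001
preprocessing,SNV-ELM,None,82.50,84.62,82.50,0.8354
preprocessing,SNV-ELM,Acetamiprid,82.50,84.62,82.50,0.8354
preprocessing,SNV-ELM,Malathion,75.00,76.92,75.00,0.7595
preprocessing,SNV-ELM,Difenoconazole,82.50,76.74,82.50,0.7952
preprocessing,SNV-ELM,Beta-cypermethrin,77.50,77.50,77.50,0.7750
optimized,NM-GA-ELM,All,88.50,88.72,88.50,0.8852
optimized,NM-GA-ELM,None,90.00,92.31,90.00,0.9114
optimized,NM-GA-ELM,Acetamiprid,95.00,90.48,95.00,0.9268
optimized,NM-GA-ELM,Malathion,87.50,92.11,87.50,0.8974
optimized,NM-GA-ELM,Difenoconazole,82.50,89.19,82.50,0.8571
optimized,NM-GA-ELM,Beta-cypermethrin,87.50,79.55,87.50,0.8333
optimized,NM-HBA-ELM,All,90.50,90.66,90.50,0.9051
optimized,NM-HBA-ELM,None,95.00,88.37,95.00,0.9157
optimized,NM-HBA-ELM,Acetamiprid,92.50,94.87,92.50,0.9367
optimized,NM-HBA-ELM,Malathion,87.50,94.59,87.50,0.9091
optimized,NM-HBA-ELM,Difenoconazole,90.00,85.71,90.00,0.8780
optimized,NM-HBA-ELM,Beta-cypermethrin,87.50,89.74,87.50,0.8861
optimized,NM-tHBA-ELM,All,93.50,93.73,93.50,0.9355
optimized,NM-tHBA-ELM,None,92.50,88.10,92.50,0.9024
optimized,NM-tHBA-ELM,Acetamiprid,95.00,97.44,95.00,0.9620
optimized,NM-tHBA-ELM,Malathion,92.50,97.37,92.50,0.9487
optimized,NM-tHBA-ELM,Difenoconazole,95.00,88.37,95.00,0.9157
optimized,NM-tHBA-ELM,Beta-cypermethrin,92.50,97.37,92.50,0.9487
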