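model,TP,TN,FP,FN,sensitivity,specificity,f1,mcc
Model I,4,82,2,11,0.267,0.976,0.381,0.365
Model II,14,83,1,1,0.933,0.988,0.933,0.921
Model II with Dataset II,4,39,1,6,0.400,0.975,0.533,0.500
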