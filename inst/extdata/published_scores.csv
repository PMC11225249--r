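dataset,flr_sensitivity,smote_flr_sensitivity,smote_knn_sensitivity,flr_specificity,smote_flr_specificity,flr_f1,smote_flr_f1,flr_mcc,smote_flr_mcc
Breast Cancer,0.874,0.995,0.644,0.914,0.937,0.818,0.938,0.725,0.845
Breast Cancer Wisconsin (Prognostic),0.880,0.992,0.568,0.844,0.971,0.830,0.976,0.795,0.829
Breast Cancer Wisconsin (Diagnostic),0.813,0.995,0.939,0.860,0.964,0.813,0.973,0.788,0.852
Hepatitis,0.799,0.993,0.567,0.902,0.954,0.801,0.942,0.798,0.852
Pima Indians Diabetes Database,0.867,0.911,0.569,0.923,0.959,0.825,0.866,0.756,0.794
Liver Disorders,0.911,0.936,0.618,0.876,0.994,0.839,0.968,0.756,0.827
SPECTF Heart,0.920,0.942,0.903,0.847,0.993,0.898,0.934,0.842,0.847
Fertility,0.937,0.953,0.497,0.683,0.891,0.927,0.883,0.756,0.830
Diabetic Retinopathy Debrecen,0.922,0.923,0.660,0.924,0.922,0.894,0.866,0.816,0.860
Breast Cancer Coimbra,0.929,0.924,0.612,0.909,0.931,0.926,0.855,0.841,0.854
Parkinson's Disease,0.913,0.926,0.621,0.828,0.840,0.898,0.843,0.786,0.812
Heart failure,0.823,0.844,0.481,0.938,0.946,0.846,0.850,0.824,0.856
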