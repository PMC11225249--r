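dataset,predictor,a1,a2,a3,crisp_estimate,odds_ratio
Breast Cancer,X4,-1.796,-1.308,-0.593,-1.232,0.292
Breast Cancer Wisconsin (Prognostic),X12,1.507,1.642,1.779,1.643,5.171
Breast Cancer Wisconsin (Diagnostic),X28,1.022,1.492,1.645,1.386,3.999
Hepatitis,Varices,-1.935,-1.595,-0.582,-1.371,0.254
Pima Indians Diabetes Database,X1,-1.772,-0.803,0.131,-0.815,0.443
Liver Disorders,alkphos,-1.087,-1.072,-0.919,-1.026,0.358
SPECTF Heart,F9S,-1.973,-1.403,-1.384,-1.587,0.205
Fertility,X3,-1.939,-1.656,0.244,-1.117,0.327
Diabetic Retinopathy Debrecen,X15,1.068,1.885,1.995,1.649,5.202
Breast Cancer Coimbra,HOMA,-1.567,-1.400,-0.780,-1.249,0.287
Parkinson's Disease,tqwt mean dec-30,1.715,1.733,1.974,1.807,6.092
Heart failure,diabetes,-1.808,-0.831,-0.530,-1.056,0.348
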