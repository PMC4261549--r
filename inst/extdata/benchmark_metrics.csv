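setting,dataset,method,sn,sp,acc,mcc,auc,tp,tn,fp,fn,sn_consistent,mcc_consistent
cv_balanced,DVI,svm_residue_cv,77.88,81.34,81.18,0.30,0.87,2349,50530,11592,667,TRUE,TRUE
cv_balanced,DVI,svm_sequence_cv,77.65,80.16,80.04,0.29,0.87,2342,49797,12325,674,TRUE,TRUE
cv_balanced,DVAI,svm_residue_cv,73.98,77.94,77.67,0.30,0.85,398,5749,1627,140,TRUE,TRUE
cv_balanced,DVAI,svm_sequence_cv,72.12,76.34,76.06,0.28,0.82,388,5631,1745,150,TRUE,FALSE
cv_balanced,DVBI,svm_residue_cv,80.44,83.83,83.68,0.33,0.90,1785,42063,8116,434,TRUE,TRUE
cv_balanced,DVBI,svm_sequence_cv,79.86,82.90,82.77,0.32,0.89,1772,41598,8581,447,TRUE,TRUE
cv_balanced,DPLPI,svm_residue_cv,91.48,93.38,93.30,0.55,0.97,999,24874,1764,93,TRUE,TRUE
cv_balanced,DPLPI,svm_sequence_cv,90.38,92.62,92.53,0.52,0.96,987,24672,1966,105,TRUE,TRUE
cv_balanced_features,DVI,pssm,77.65,80.16,80.04,0.29,0.87,2342,49797,12325,674,TRUE,TRUE
cv_balanced_features,DVI,pssm_psss_vbps,78.55,82.02,81.86,0.31,0.88,2369,50951,11171,647,TRUE,TRUE
cv_balanced_features,DVAI,pssm,72.12,76.34,76.06,0.28,0.82,388,5631,1745,150,TRUE,FALSE
cv_balanced_features,DVAI,pssm_psss_vbps,72.12,78.28,77.86,0.29,0.84,388,5774,1602,150,TRUE,TRUE
cv_balanced_features,DVBI,pssm,79.86,82.90,82.77,0.32,0.89,1772,41598,8581,447,TRUE,TRUE
cv_balanced_features,DVBI,pssm_psss_vbps,80.71,85.14,84.96,0.35,0.90,1791,42724,7455,428,TRUE,TRUE
cv_balanced_features,DPLPI,pssm,90.38,92.62,92.53,0.52,0.96,987,24672,1966,105,TRUE,TRUE
cv_balanced_features,DPLPI,pssm_psss_vbps,91.48,93.09,93.03,0.54,0.97,999,24798,1840,93,TRUE,TRUE
ind_balanced,DVI,svm_sequence_cv,75.38,78.51,78.35,0.28,0.85,493,9167,2509,161,TRUE,TRUE
ind_balanced,DVI,targetvita,80.73,81.05,81.03,0.33,0.89,528,9463,2213,126,TRUE,TRUE
ind_balanced,DVAI,svm_sequence_cv,73.48,79.25,78.61,0.38,0.83,133,1142,299,48,TRUE,TRUE
ind_balanced,DVAI,targetvita,79.01,79.18,79.16,0.41,0.86,143,1141,300,38,TRUE,TRUE
ind_balanced,DVBI,svm_sequence_cv,78.28,81.49,81.35,0.30,0.88,328,7291,1656,91,TRUE,TRUE
ind_balanced,DVBI,targetvita,81.38,81.69,81.68,0.32,0.90,341,7309,1638,78,TRUE,TRUE
ind_balanced,DPLPI,svm_sequence_cv,85.77,90.18,90.00,0.44,0.95,211,5352,583,35,TRUE,TRUE
ind_balanced,DPLPI,targetvita,89.02,89.30,89.29,0.44,0.96,219,5300,635,27,TRUE,TRUE
ind_maxmcc,DVI,svm_sequence_cv,47.09,98.40,95.68,0.52,0.85,308,11489,187,346,TRUE,TRUE
ind_maxmcc,DVI,targetvita,47.01,98.42,95.69,0.52,0.89,308,11491,185,346,FALSE,TRUE
ind_maxmcc,DVAI,svm_sequence_cv,32.04,97.09,89.83,0.38,0.83,58,1399,42,123,TRUE,TRUE
ind_maxmcc,DVAI,targetvita,38.12,96.81,90.26,0.43,0.86,69,1395,46,112,TRUE,TRUE
ind_maxmcc,DVBI,svm_sequence_cv,52.03,98.25,96.18,0.53,0.88,218,8790,157,201,TRUE,TRUE
ind_maxmcc,DVBI,targetvita,51.06,98.69,96.56,0.55,0.90,214,8830,117,205,FALSE,FALSE
ind_maxmcc,DPLPI,svm_sequence_cv,72.76,99.11,98.06,0.74,0.95,179,5882,53,67,TRUE,TRUE
ind_maxmcc,DPLPI,targetvita,74.39,99.07,98.09,0.75,0.96,183,5880,55,63,TRUE,TRUE
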