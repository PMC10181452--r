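study,label,n,sum,mean,variance
personalized_m2_6,direct,14,86.756,6.197,4.672
personalized_m2_6,one_synergy,14,107.930,7.709,7.335
personalized_m2_6,two_synergy,14,108.972,7.784,7.748
cross_subject_m2_6,direct,196,2157.122,11.006,42.696
cross_subject_m2_6,one_synergy,196,2025.910,10.336,19.789
cross_subject_m2_6,two_synergy,196,1895.985,9.673,18.365
cross_subject_m2_2,direct,196,2792.539,14.248,41.462
cross_subject_m2_2,one_synergy,196,2646.628,13.503,24.561
cross_subject_m2_2,two_synergy,196,2440.454,12.451,23.557
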