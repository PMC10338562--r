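subject,vo2max_exp,vo2max_smo,delta_smo,vo2max_jurca,delta_jurca
S1,3.54,3.47,1.9,3.09,12.7
S2,4.57,4.80,5.1,4.20,8.1
S3,4.34,3.76,13.4,4.16,4.1
S4,3.35,3.55,6.1,3.41,1.9
S5,4.58,4.98,8.7,4.02,12.3
S6,3.29,3.23,1.9,2.71,17.8
S7,4.02,4.20,4.5,4.36,8.5
S8,3.68,3.64,1.2,3.00,18.5
S9,3.97,4.26,7.4,3.68,7.5
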