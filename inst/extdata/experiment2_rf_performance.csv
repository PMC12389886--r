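subject,accuracy,precision,recall,f1
1,91.43,88.36,95.47,91.78
2,89.58,90.53,90.98,90.75
3,87.40,84.80,88.30,86.51
4,80.96,73.81,90.46,81.29
5,94.97,91.21,94.20,92.68
6,87.99,76.88,84.34,80.44
7,91.38,85.84,84.36,85.09
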