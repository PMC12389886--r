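subject,accuracy,precision,recall,f1
1,92.18,89.54,95.57,92.45
2,86.59,84.61,93.09,88.64
3,86.09,78.76,95.33,86.25
4,80.32,70.15,99.15,82.16
5,93.77,87.66,94.95,91.15
6,86.07,69.25,94.24,79.83
7,90.28,80.26,88.46,84.16
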