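"class_id","b443","b490","b560","b665","b708","b778","b865"
1,0.012925,0.012854,0.02,0.00386,0.002543,0.001586,0.000811
2,0.011492,0.011953,0.02,0.004116,0.002907,0.001832,0.000816
3,0.02,0.015816,0.014409,0.007913,0.006857,0.004401,0.001715
4,0.011192,0.011718,0.02,0.006076,0.005075,0.003262,0.001134
5,0.00864,0.010124,0.02,0.006075,0.005221,0.00337,0.001068
6,0.016496,0.014837,0.02,0.014214,0.013708,0.008923,0.002626
7,0.008964,0.010225,0.02,0.010294,0.009834,0.006407,0.001779
8,0.005873,0.008326,0.02,0.008939,0.008523,0.005559,0.001473
9,0.008779,0.009931,0.02,0.017743,0.018024,0.011803,0.003014
10,0.006077,0.008261,0.02,0.016957,0.017314,0.011349,0.002813
11,0.003182,0.006559,0.02,0.012527,0.012616,0.008268,0.002
12,0.00302,0.00583,0.018075,0.01916,0.02,0.013135,0.003116
13,0.001536,0.003909,0.013971,0.018904,0.02,0.013148,0.003069
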