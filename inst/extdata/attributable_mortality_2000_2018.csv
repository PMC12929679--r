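age_group,sex,attributable,ci_low,ci_high,total_deaths
35-44,F,591,-538,1696,97536
45-54,F,4864,1945,7732,311442
55-64,F,13070,8057,18008,624238
65-74,F,13976,6885,20959,878866
75-84,F,12397,5383,19321,1010316
85+,F,9451,4146,14678,670248
35-44,M,260,-753,1248,73665
45-54,M,3145,-5,6235,307074
55-64,M,12611,6380,18745,746782
65-74,M,20912,12591,29109,1062167
75-84,M,17968,10599,25243,1105497
85+,M,6341,2274,10352,559185
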