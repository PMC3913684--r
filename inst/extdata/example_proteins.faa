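>g001 # 101 # 600 # 1 # ID=g001;partial=00
MKKLDRETVISAAMKVFARHGYHGTSMQDIADELGISKGSLYYHFKSKEELFLEVVNEGM
>g002 # 701 # 1200 # -1 # ID=g002;partial=00
MSNELVVKSNKLNQALHTLSPKQQQVLWLRYFEGLSYKEIAEITGLSVKAVEGHIYRGLSQLRKVMEEGE
>g003 # 1 # 450 # 1 # ID=g003;partial=10
MGRKPKTLTEDEVQRLLAACRSSNSIRDYCIILLAFRHGLRISELLDLHYQDLDFNEQTI
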