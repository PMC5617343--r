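post_id,NumPost,NumUser,AvgLen,NumName,NumNeg,NumPos,NumCAM,NumOverlap,Num?,Num!,TimeDif,Sig,NAgree,NDisagree
p000001,5,2,25.8,0,0,0,0,0,0,0,0,0,0,0
p000004,5,2,25.8,1,0,0,2,7,1,0,911,1,0,0
p000007,5,2,25.8,0,0,0,0,5,0,1,485,0,0,0
p000010,5,2,25.8,0,0,0,0,1,0,0,841,0,0,0
p000013,8,4,31.25,1,0,0,2,4,2,1,7740,0,0,1
p000016,8,4,31.25,1,0,0,0,3,0,1,4785,0,0,1
p000019,6,4,24.333333333333332,0,0,0,0,0,0,0,0,0,0,0
p000022,6,4,24.333333333333332,0,0,0,0,5,0,0,4219,0,0,0
p000025,7,5,24.714285714285715,0,0,0,0,0,1,0,0,0,0,0
p000028,7,5,24.714285714285715,0,0,0,0,4,0,0,469,1,0,0
p000031,7,5,24.714285714285715,0,0,0,0,6,0,0,2949,0,0,0
p000034,7,5,21.142857142857142,0,0,0,0,2,0,0,1826,0,0,0
p000037,7,5,21.142857142857142,0,0,0,0,6,0,0,1393,0,0,0
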