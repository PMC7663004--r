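region,tp,fn,fp,gt
Field 1-Blue,198,25,1,223
Field 1-Purple,336,33,9,369
Field 1-Red,344,70,11,414
Field 2-Blue,326,60,25,386
Field 2-Purple,99,6,13,105
Field 2-Red,177,8,7,185
Field 3-Blue,101,2,10,103
Field 3-Purple,192,7,25,199
Field 3-Red,78,5,15,83
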