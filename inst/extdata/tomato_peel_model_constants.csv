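model,temperature_C,param,value
newton,50,k,0.5096
newton,55,k,0.5989
newton,60,k,0.6271
newton,65,k,0.7691
newton,70,k,1.0250
newton,75,k,1.2920
page,50,k,0.5854
page,50,n,0.8494
page,55,k,0.6901
page,55,n,0.8143
page,60,k,0.6904
page,60,n,0.8661
page,65,k,0.8978
page,65,n,0.7331
page,70,k,1.1523
page,70,n,0.6865
page,75,k,1.3681
page,75,n,0.7399
modified_page,50,k,0.5324
modified_page,50,n,0.8494
modified_page,55,k,0.6341
modified_page,55,n,0.8143
modified_page,60,k,0.6519
modified_page,60,n,0.8661
modified_page,65,k,0.8633
modified_page,65,n,0.7331
modified_page,70,k,1.2294
modified_page,70,n,0.6865
modified_page,75,k,1.5274
modified_page,75,n,0.7399
two_term,50,a,0.3204
two_term,50,k1,0.2673
two_term,50,b,0.6800
two_term,50,k2,0.7452
two_term,55,a,0.1957
two_term,55,k1,0.2180
two_term,55,b,0.8062
two_term,55,k2,0.8145
two_term,60,a,0.1455
two_term,60,k1,0.2194
two_term,60,b,0.8568
two_term,60,k2,0.7801
two_term,65,a,0.3408
two_term,65,k1,0.3562
two_term,65,b,0.6593
two_term,65,k2,1.3215
two_term,70,a,0.2667
two_term,70,k1,0.4049
two_term,70,b,0.7333
two_term,70,k2,1.6353
two_term,75,a,0.0769
two_term,75,k1,0.2581
two_term,75,b,0.9232
two_term,75,k2,1.5304
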