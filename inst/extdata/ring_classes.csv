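priority,class,condition,value,note
1,HC,pair45,H:C,"C3HC4: His at metal position 4, Cys at 5"
2,H2,pair45,H:H,"C3H2C3: His at metal positions 4 and 5"
3,v,pair45,C:H,"variant RING-v (CH): Cys at 4, His at 5"
4,C2,all_cys,,"RING-C2: cysteines at all eight metal positions"
5,D,any,D,"Asp at any metal position"
6,S/T,any,S:T,"Ser or Thr at any metal position"
7,G,any,G,"Gly at any metal position (absent from most tallies)"
8,non-canonical,default,,fallback
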