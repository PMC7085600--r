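user,step,k,n
1,0,50,50
1,1,49,50
1,2,47,50
1,3,46,50
1,4,44,50
1,5,49,50
1,6,48,50
2,0,49,50
2,1,49,50
2,2,45,50
2,3,42,50
2,4,41,50
2,5,47,50
2,6,47,50
3,0,50,50
3,1,49,50
3,2,48,50
3,3,45,50
3,4,43,50
3,5,49,50
3,6,49,50
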