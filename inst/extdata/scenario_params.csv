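scenario,Xm,vm,lam,Kx,mx,ax,Kv,mv,av,Kl,ml,al
A,1.00,0.25,3.00,1.00,5.00,2.00,1.00,4.00,2.00,1.00,2.00,2.00
B,1.00,0.25,3.00,1.00,5.00,2.00,1.00,4.00,2.00,NA,NA,NA
C,1.00,0.25,3.00,1.00,5.00,2.00,NA,NA,NA,NA,NA,NA
D,1.00,0.25,3.00,1.00,5.00,2.00,NA,NA,NA,1.00,2.00,2.00
E,1.00,0.50,4.00,NA,NA,NA,0.60,3.00,2.00,4.00,10.00,2.00
F,1.00,0.20,5.00,NA,NA,NA,0.60,8.00,2.00,NA,NA,NA
G,1.00,0.50,4.00,NA,NA,NA,NA,NA,NA,4.00,10.00,2.00
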