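case,protein,time_unit,conc_unit,response_unit,Xm,vm,lam,Kx,mx,ax,Kv,mv,av,Kl,ml,al
egcg_1,insulin,h,mM,AU,1.12,0.18,4.78,0.43,0.68,1.65,NA,NA,NA,0.81,0.50,0.98
egcg_2,insulin,h,mM,AU,1.28,0.25,53.34,0.94,0.01,0.96,NA,NA,NA,NA,NA,NA
dic7pc,insulin,h,mM,%,99.85,1.55,124.62,0.75,0.65,4.04,0.86,0.47,2.51,NA,NA,NA
methylglyoxal,insulin,h,mM,AU,541.20,219.68,2.92,1.00,1.80,0.99,0.99,0.42,0.74,NA,NA,NA
apigenin,abeta42,h,uM,AU,17.43,16.10,0.25,0.41,6.52,0.91,0.38,9.29,1.35,1.76,2.16,2.39
ectoine,abeta42,h,mM,AU,0.00507,0.00024,11.60,1.00,11.82,0.19,0.83,0.33,0.36,NA,NA,NA
hydroxyectoine,abeta42,h,mM,AU,0.00496,0.00030,13.50,1.00,66.70,0.43,0.86,1.35,0.34,NA,NA,NA
taiwaniaflavone,abeta42,h,uM,AU,16.55,17.01,0.27,0.78,2.32,0.98,1.14,1.88,0.40,1.27,2.53,2.33
trehalose,apomyoglobin,d,mM,AU,10.49,3.31,5.76,0.44,51.58,1.36,0.53,33.22,0.66,NA,NA,NA
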