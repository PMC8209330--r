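feature,label,mean_decrease_gini
m1,first-order moment,1.7897453
c1,first-order central moment,0.8495841
a1,first-order absolute moment,0.7873654
m2,second-order moment,1.8026458
c2,second-order central moment,1.5147000
a2,second-order absolute moment,1.3757714
m3,third-order moment,1.6430335
c3,third-order central moment,1.8037972
a3,third-order absolute moment,1.8316361
m4,fourth-order moment,2.0892720
c4,fourth-order central moment,1.0609800
a4,fourth-order absolute moment,1.4124922
energy,energy,0.4763909
entropy,entropy,0.5165798
inertia,inertia moment,0.7618972
correlation,correlation,0.7355067
homogeneity,homogeneity,0.8385106
dissimilarity,dissimilarity,0.7343357
glcm_mean,mean,1.7526929
glcm_variance,variance,1.9482926
glcm_sd,standard deviation,3.1126458
lre,long run emphasis,0.8664384
sre,short run emphasis,1.4297721
rp,total run-length percentage,0.8314745
gln,gray level nonuniformity,0.4918337
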