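trait,abbreviation,unit,mean,min,max,h2
Shoot dry weight,SDW,g,0.039,0.018,0.059,0.57
Total dry weight,TDW,g,0.053,0.024,0.080,0.51
Root dry weight,RDW,g,0.014,0.006,0.022,0.39
Total root respiration,TRR,nmol CO2 s-1,0.54,0.23,0.91,0.42
SRR per root length,SRR_L,nmol CO2 s-1 m-1,0.14,0.04,0.34,0.48
SRR per root mass,SRR_M,nmol CO2 s-1 g-1,39.86,23.32,74.79,0.32
SRR residual,SRR_R,nmol CO2 s-1,-0.0039,-0.3623,0.27,0.44
Specific root length,SRL,m g-1,299.7,182.21,398.36,0.55
Root mass fraction,RMF,%,26.48,19.05,36.17,0.43
Total root length,TRL,mm,4125.91,1315.65,7861.83,0.47
Axial root length,ARL,mm,1456.2,655.59,2537.42,0.48
Lateral root length,LRL,mm,2669.71,660.06,5494.75,0.48
Lateral:axial root length ratio,L_A_L,mm mm-1,1.82,0.83,2.66,0.48
Total root volume,TRV,mm3,329.49,135.78,610.24,0.45
Axial root volume,ARV,mm3,243.9,113.64,459.5,0.46
Lateral root volume,LRV,mm3,85.59,22.15,164.09,0.40
Lateral:axial root volume ratio,L_A_V,mm3 mm-3,0.36,0.17,0.53,0.45
Total root surface area,TSA,mm2,3680.62,1348.64,6477.28,0.45
Axial root surface area,ASA,mm2,2034.03,934.42,3639.73,0.47
Lateral root surface area,LSA,mm2,1646.59,414.22,3266.23,0.44
Average root diameter,AvgD,mm,0.29,0.25,0.37,0.53
Number of root tips,Tip,n,399.61,161.67,710,0.40
Number of branch points,BP,n,931.66,283,1992.5,0.54
Branching frequency,BF,n mm-1,0.22,0.18,0.31,0.45
Branching density,BD,n cm-1,2.81,1.75,5.83,0.25
Root tissue density,RTD,g cm-3,0.04,0.03,0.06,0.30
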