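waterbody,meadow,code,size_ha,impact,n_ind,n_mll,cluster,areal_change_pct
N Bohuslans skargards kust,Koster donor,KOD,7.5,reference,17,8,C1,NA
N yttre Tjarnoarkipelago,Gasholmen,GAS,NA,impacted,20,11,C3,NA
Fjallbacka inre skargard,Kampersvik,KAV,2.7,impacted,20,13,C1,NA
Fjallbacka inre skargard,Jorefjorden,JOR,169.4,reference,19,16,C1,NA
Brofjorden,Hanneviken,HAV,34.2,impacted,19,2,NA,100
Getevikssund,Lindholmen,LIN,10.2,reference,20,12,C1,NA
Gullmarn centralbassang,Fiskebackskil,FIS,1.9,impacted,20,18,C2,NA
Koljo fjord,Vast Hjalton,VHA,31.6,reference,20,17,C2,NA
Kalvofjord,Vast Flatholmen,VFL,0.4,impacted,20,13,C3,NA
Stigfjorden,Svanvik,SVA,1.9,impacted,20,12,C4,NA
Stigfjorden,Vik,VIK,51,reference,20,14,C4,NA
Hake fjord,Stenungsund,STE,47.1,reference,20,16,C5,NA
Hake fjord,Kakenas,KAK,47.1,reference,20,16,C5,NA
Hake fjord,Wallhamn,WAL,6.7,impacted,19,13,C5,NA
Algofjorden,N Inston,NIN,6.4,reference,15,13,C5,NA
Nordre Alvs fjord,N Overon,NOV,4.2,reference,13,9,C5,NA
Branno-Styrsoomradet,S Branno,SBR,55.2,impacted,19,19,C5,NA
Halsviken,Halsvik,HAL,34.5,reference,20,11,C5,NA
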