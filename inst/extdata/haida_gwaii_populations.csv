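abbreviation,population,habitat,depth_m,area_ha,t400,blackwater,watershed,year,n
ANSR,Anser,lake,4.0,18.0,76.0,no,Kumara,2009,1
BK70,Banks 70,lake,3.0,5.0,91.0,no,Banks 70,2010,1
BKW2,Banks W2,lake,2.0,2.0,85.0,no,Banks W2,2010,1
BOUL,Boulton,lake,4.0,15.0,78.1,no,Masset inlet,2010,2
BRNT,Branta,lake,4.0,3.0,70.0,yes,Sangan,2009,1
COAT,Coates,lake,30.0,90.0,94.5,no,Coates,2009,1
DARW,Darwin,lake,15.0,13.9,90.0,no,Darwin,2009,1
DAWS,Dawson,lake,4.0,1.0,82.0,no,Dawson,2009,1
DRIZ,Drizzle,lake,16.0,97.0,67.0,yes,Sangan,2009,4
EDEN,Eden,lake,50.0,513.0,87.0,no,Naden,2010,1
ESCP,Escarpment,lake,50.0,97.0,93.6,no,Barry,1993,1
GOLD,Gold Creek,stream,NA,NA,50.2,yes,Mayer,2009,2
LAUR,Laurel,lake,2.0,2.0,70.0,yes,Sangan,1993,1
LUTE,Lutea,lake,2.0,3.0,93.9,no,Burnaby,2003,1
MAYR,Mayer Lake,lake,20.0,489.9,57.1,yes,Mayer,2004,12
MNYN,Menyanthes,lake,5.0,6.0,82.0,no,Hughes,2009,1
MDPC,Mid-Pacific,marine,NA,NA,NA,no,NA,1993,1
POQU,Poque,lake,25.0,17.0,90.8,no,Poque,2009,1
RDSP,Roadside Pond,lake,1.0,0.3,80.0,no,NA,2012,11
ROUG,Rouge,lake,2.0,1.2,68.1,yes,Kliki,2000,1
SDPY,Serendipity,lake,2.0,3.0,70.5,yes,Hiellen,2006,1
SKID,Skidegate,lake,4.0,8.5,60.0,yes,Copper,2009,1
SKON,Skonun,lake,20.0,734.0,94.4,no,Sangan,2009,1
SLTC,Solstice,lake,15.0,51.0,68.0,yes,Sangan,2009,1
SLVR,Silver,lake,5.0,11.7,72.2,yes,Kumara,2009,1
SPNC,Spence,lake,30.0,95.0,75.0,no,Hiellen,2009,4
STIU,Stiu,lake,30.0,24.0,92.8,no,Stiu,2009,1
WATT,Watt,lake,2.0,4.0,60.0,yes,Mayer,2009,1
WDPL,Woodpile,lake,2.0,4.0,60.8,yes,Mayer,2009,1
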