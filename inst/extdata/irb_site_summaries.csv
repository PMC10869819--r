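# Site-level metabolism summaries for 17 Illinois River Basin sites,
# transcribed from the USGS data release doi:10.5066/P9TEBOUR summary
# tables. Units: discharge m3/s; GPP, ER, NEP g O2 m-2 d-1; percents 0-100.
site_name,nwis_no,river_group,n_days_unflagged,pct_unflagged,q_mean,q_sd,gpp_mean,gpp_sd,er_mean,er_sd,nep_mean,pct_autotrophic,depth_method,confidence
ILLINOIS RIVER AT FLORENCE IL,05586300,Illinois mainstem,1888,73,892.1,670.4,2.22,2.28,-6.14,4.37,-3.92,14,rating,LOW
ILLINOIS RIVER AT HENRY IL,05558300,Illinois mainstem,444,68,532.0,423.3,2.41,2.29,-7.44,4.55,-4.98,22,hydraulic,HIGH
ILLINOIS RIVER AT STARVED ROCK IL,05553700,Illinois mainstem,398,59,348.4,327.3,4.87,4.33,-5.17,4.82,-0.30,56,hydraulic,MEDIUM
ILLINOIS RIVER AT SENECA IL,05543010,Illinois mainstem,337,32,353.2,293.4,4.14,3.49,-8.01,6.06,-3.87,39,rating,MEDIUM
FOX RIVER NEAR MCHENRY IL,05549500,Fox,351,95,123.6,12.8,8.64,5.04,-7.79,4.22,0.85,47,rating,LOW
FOX RIVER AT ALGONQUIN IL,05550001,Fox,351,84,47.1,42.1,5.62,3.01,-6.83,4.19,-1.21,38,rating,MEDIUM
DES PLAINES RIVER AT ROUTE 53 AT JOLIET IL,05537980,Des Plaines,767,75,135.7,92.6,3.76,2.07,-8.78,2.21,-5.02,5,rating,MEDIUM
DES PLAINES RIVER AT ROCKDALE IL,05538010,Des Plaines,174,42,118.4,67.4,0.70,1.15,-7.57,3.76,-6.87,1,hydraulic,MEDIUM
DES PLAINES RIVER IN LOCK CHANNEL AT ROCKDALE IL,05538020,Des Plaines,266,44,24.9,66.8,1.09,0.99,-4.41,3.39,-3.32,10,hydraulic,MEDIUM
KANKAKEE RIVER AT SHELBY IN,05518000,Kankakee,1325,89,61.2,29.4,0.45,0.69,-3.78,2.28,-3.35,1,rating,HIGH
KANKAKEE RIVER AT DUNNS BRIDGE IN,05517500,Kankakee,556,96,47.2,25.7,0.59,0.51,-4.23,1.90,-3.65,2,rating,HIGH
KANKAKEE RIVER AT DAVIS IN,05515500,Kankakee,1630,88,19.6,8.2,1.01,0.85,-5.42,2.11,-4.41,0,rating,HIGH
IROQUOIS RIVER NEAR FORESMAN IN,05524500,tributary,439,83,12.4,13.8,2.47,3.56,-5.79,3.84,-3.32,16,rating,HIGH
GRAND CALUMET RIVER AT COLUMBIA AV AT HAMMOND IN,05536356,tributary,167,94,4.2,0.7,1.64,0.79,-2.56,0.96,-0.92,16,hydraulic,HIGH
LICK CREEK NEAR WOODSIDE IL,05576100,tributary,453,67,1.3,2.5,2.67,3.03,-7.84,3.39,-5.17,12,rating,LOW
SUGAR CREEK NEAR CHATHAM IL,05576195,tributary,234,28,1.7,6.1,2.39,2.29,-7.46,4.54,-5.06,18,rating,LOW
KICKAPOO CREEK NEAR BLOOMINGTON IL,05579630,tributary,1158,92,0.4,1.8,2.32,2.35,-3.61,2.85,-1.29,23,rating,HIGH
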