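held_out_season,site,full_error,lowest_error,zeroed_coefficient
2019,Manhattan,7211,4099,VPD
2019,Goodland,15003,5963,NO3
2019,Garden City,23795,13366,Tmin
2020,Keats,280461,10283,P
2020,Greensburg,236793,56352,NO3
2020,Goodland,39840,39840,
2020,Garden City,19574,19574,
2020,Colby B,272656,27344,PTQ
2020,Colby A,42732,27631,P
2020,Buhler,191106,1653,P
2021,Selkirk,40372,9770,VPD
2021,Keats,9477,7280,GDD
2021,Greensburg,25012,11851,Tmin
2021,Goodland,12594,6547,GDD
2021,Garden City,12847,1058,Tmax
2021,Colby A,19507,8579,GDD
2021,Buhler,2564,912,VPD
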