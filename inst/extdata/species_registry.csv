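species,family,k,se,unit,m,l_min,l_max,range_source,ecology,corr_sign,d0,printed_intercept,printed_slope
Chrysomya albiceps,Calliphoridae,143.52,5.61,ADD,7,5,12,source I,necrophagous,negative,NA,174.74,-3.67
Lucilia sericata,Calliphoridae,6023.2,297.2,ADH,7,5,12,source I,necrophagous,negative,NA,7676.99,-194.56
Phormia regina,Calliphoridae,281,3.6,ADD,5,6,10,source I,necrophagous,negative,NA,308.89,-3.49
Fannia canicularis,Fanniidae,481.73,9.89,ADD,8,3.5,7,source I,necrophagous,negative,NA,554.41,-13.84
Necrobia rufipes,Cleridae,591,39.53,ADD,6,3.5,7,source III,predatory,negative,NA,842.57,-47.92
Omosita colon,Nitidulidae,514.1,8.7,ADD,6,2,3.6,source II,necrophagous,negative,NA,578.69,-23.07
Necrodes littoralis,Silphidae,469.89,24.59,ADD,8,15,25,source I,necrophagous,negative,8.5,710.82,-12.05
Thanatophilus sinuatus,Silphidae,360.46,10.75,ADD,7,9,12,source I,necrophagous,negative,NA,532.88,-16.42
Thanatophilus rugosus,Silphidae,362.758,4.97,ADD,6,8,12,source I,necrophagous,negative,NA,415.47,-5.27
Creophilus maxillosus,Staphylinidae,405.156,14.63,ADD,8,15,25,source I,predatory,negative,11.7,548.5,-7.17
Nasonia vitripennis,Pteromalidae,4768.8,431.5,ADH,6,1.3,2.2,source I,parasitoid,positive,NA,8328.49,2034.1
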