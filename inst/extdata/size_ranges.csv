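species,l_min,l_max,source
Chrysomya albiceps,5,12,source I
Chrysomya albiceps,6,9,wikipedia
Lucilia sericata,5,12,source I
Lucilia sericata,10,14,wikipedia
Phormia regina,6,10,source I
Fannia canicularis,3.5,7,source I
Fannia canicularis,4.5,7,source II
Fannia canicularis,3.5,6,wikipedia
Necrobia rufipes,3.5,4.5,source I
Necrobia rufipes,4,5.5,source II
Necrobia rufipes,3.5,7,source III
Necrobia rufipes,3.5,7,wikipedia
Omosita colon,2,3.6,source I
Omosita colon,2,3.6,source II
Omosita colon,2,3.5,wikipedia
Necrodes littoralis,15,25,source I
Necrodes littoralis,16,25,source II
Necrodes littoralis,12,22,source III
Necrodes littoralis,15,25,wikipedia
Thanatophilus sinuatus,9,12,source I
Thanatophilus sinuatus,9,12,source II
Thanatophilus sinuatus,9,12,wikipedia
Thanatophilus rugosus,8,12,source I
Thanatophilus rugosus,10,13,source II
Thanatophilus rugosus,10,14,wikipedia
Creophilus maxillosus,15,25,source I
Creophilus maxillosus,15,23,source II
Creophilus maxillosus,15,24,source III
Creophilus maxillosus,12,18,wikipedia
Nasonia vitripennis,1.3,2.2,source I
Nasonia vitripennis,2,3,wikipedia
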