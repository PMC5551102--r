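species,family,s50,sex_expression,leaf_habit,fruit_type,dbh95_cm,n_obs
Magnolia obovata,Magnoliaceae,0.358,cosexual,deciduous,fleshy,56.1,41
Magnolia salicifolia,Magnoliaceae,0.377,cosexual,deciduous,fleshy,30.3,66
Neolitsea aciculata,Lauraceae,0.244,dioecious,evergreen,fleshy,23.4,131
Neolitsea sericea,Lauraceae,0.113,dioecious,evergreen,fleshy,26.0,58
Litsea coreana,Lauraceae,0.284,dioecious,evergreen,fleshy,71.0,21
Machilus japonica,Lauraceae,0.372,cosexual,evergreen,fleshy,38.1,45
Cinnamomum yabunikkei,Lauraceae,0.081,cosexual,evergreen,fleshy,30.7,47
Symplocos prunifolia,Symplocaceae,0.668,cosexual,evergreen,fleshy,20.3,34
Styrax japonica,Styracaceae,0.186,cosexual,deciduous,dry,25.3,58
Pieris japonica,Ericaceae,0.537,cosexual,evergreen,dry,16.3,73
Lyonia ovalifolia,Ericaceae,0.397,cosexual,deciduous,dry,10.3,73
Clethra barbinervis,Clethraceae,0.393,cosexual,deciduous,dry,18.2,71
Camellia japonica,Theaceae,0.214,cosexual,evergreen,dry,33.1,40
Eurya japonica,Pentaphylacaceae,0.210,dioecious,evergreen,fleshy,7.9,76
Gamblea innovans,Araliaceae,0.216,dioecious,deciduous,fleshy,30.3,52
Chengiopanax sciadophylloides,Araliaceae,0.280,cosexual,deciduous,fleshy,29.6,58
Aralia elata,Araliaceae,0.150,cosexual,deciduous,fleshy,16.2,38
Ilex pedunculosa,Aquifoliaceae,0.140,dioecious,evergreen,fleshy,28.3,81
Osmanthus heterophyllus,Oleaceae,0.101,dioecious,evergreen,fleshy,23.7,82
Ligustrum japonicum,Oleaceae,0.277,cosexual,evergreen,fleshy,12.8,31
Cornus macrophylla,Cornaceae,0.388,cosexual,deciduous,fleshy,40.4,47
Castanopsis cuspidata,Fagaceae,0.358,cosexual,evergreen,dry,54.2,40
Photinia glabra,Rosaceae,0.220,cosexual,evergreen,fleshy,40.7,40
Laurocerasus spinulosa,Rosaceae,0.284,cosexual,evergreen,fleshy,57.6,22
Mallotus japonicus,Euphorbiaceae,0.062,dioecious,deciduous,dry,34.8,91
Zanthoxylum piperitum,Rutaceae,0.136,dioecious,deciduous,dry,6.4,41
Zanthoxylum ailanthoides,Rutaceae,0.221,dioecious,deciduous,dry,46.9,70
Acer palmatum,Sapindaceae,0.327,cosexual,deciduous,dry,38.4,57
Acer rufinerve,Sapindaceae,0.087,dioecious,deciduous,dry,35.3,155
Illicium anisatum,Schisandraceae,0.422,cosexual,evergreen,dry,16.6,50
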