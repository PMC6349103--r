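genus,clade
Salvia,Nepetoideae
Mentha,Nepetoideae
Origanum,Nepetoideae
Isodon,Nepetoideae
Hyptis,Nepetoideae
Perovskia,Nepetoideae
Nepeta,Nepetoideae
Melissa,Nepetoideae
Rosmarinus,Nepetoideae
Thymus,Nepetoideae
Ocimum,Nepetoideae
Plectranthus,Nepetoideae
Lavandula,Nepetoideae
Prunella,Nepetoideae
Agastache,Nepetoideae
Dracocephalum,Nepetoideae
Glechoma,Nepetoideae
Hyssopus,Nepetoideae
Pogostemon,Lamioideae
Marrubium,Lamioideae
Leonotis,Lamioideae
Leonurus,Lamioideae
Lamium,Lamioideae
Stachys,Lamioideae
Sideritis,Lamioideae
Ballota,Lamioideae
Phlomis,Lamioideae
Galeopsis,Lamioideae
Ajuga,Ajugoideae
Teucrium,Ajugoideae
Clerodendrum,Ajugoideae
Rotheca,Ajugoideae
Caryopteris,Ajugoideae
Trichostema,Ajugoideae
Vitex,Viticoideae
Tectona,Tectonoideae
Scutellaria,Scutellarioideae
Holmskioldia,Scutellarioideae
Prostanthera,Prostantheroideae
Westringia,Prostantheroideae
Hemigenia,Prostantheroideae
Callicarpa,Callicarpoideae
Premna,Premnoideae
Gmelina,Premnoideae
Symphorema,Symphorematoideae
Congea,Symphorematoideae
Sphenodesme,Symphorematoideae
Cymaria,Cymarioideae
Acrymia,Cymarioideae
Peronema,Peronematoideae
Garrettia,Peronematoideae
Petraeovitex,Peronematoideae
Hymenopyramis,Peronematoideae
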