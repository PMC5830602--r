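site_id,beach,latitude,longitude
Sahy,Barra do Sahy,-23.77500,-45.69444
Bal,Baleia,-23.77444,-45.67528
Pal,Palmeiras,-23.69389,-45.42944
Fr1,Flecheiras 1,-23.64361,-45.42306
Fr2,Flecheiras 2,-23.63750,-45.41972
Cid1,Cidade 1,-23.62333,-45.40583
Cid2,Cidade 2,-23.62278,-45.40056
Cid3,Cidade 3,-23.61750,-45.39917
Cid4,Cidade 4,-23.62528,-45.39833
Cam,Camaroeiro,-23.62778,-45.39694
Faz1,Fazenda 1,-23.35861,-44.85611
Faz2,Fazenda 2,-23.36694,-44.83889
Toq,Toque-Toque,-23.83444,-45.51083
Pic,Picinguaba,-23.37750,-44.83806
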