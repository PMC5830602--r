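site_id,beach,width_m,slope_ratio,mean_diameter_phi,sorting_phi,caco3_pct,om_pct,beach_index
Sahy,Barra do Sahy,50,0.064,2.29,0.63,2.38,0.44,2.13
Bal,Baleia,140,0.023,2.65,0.39,7.33,0.49,2.5
Pal,Palmeiras,80,0.021,3.42,0.34,3.39,1.20,2.62
Fr1,Flecheiras 1,80,0.035,2.69,0.77,2.49,1.09,2.32
Fr2,Flecheiras 2,55,0.047,3.09,0.68,3.89,1.07,2.24
Cid1,Cidade 1,115,0.02,2.89,0.69,4.33,0.74,2.59
Cid2,Cidade 2,35,0.04,1.43,0.90,1.47,0.48,2.08
Cid3,Cidade 3,60,0.018,2.25,0.96,2.88,0.53,2.55
Cid4,Cidade 4,50,0.032,2.32,1.07,2.32,0.59,2.32
Cam,Camaroeiro,50,0.028,2.43,0.95,3.21,0.43,2.39
Faz1,Fazenda 1,100,0.016,3.21,0.29,4.08,0.43,2.72
Faz2,Fazenda 2,140,0.013,3.20,0.29,1.18,0.48,2.81
Toq,Toque-Toque,40,0.105,1.14,0.85,4.33,0.22,1.61
Pic,Picinguaba,25,0.1,0.94,0.67,0.35,0.32,1.59
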