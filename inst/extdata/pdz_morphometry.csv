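pdz,length_km,channel_length_km,width_km,water_area_km2,landmark_area_km2,n_water_masses,n_tributaries,volume_km3,mean_depth_m_printed,watershed_area_km2,cumulated_watershed_km2_printed,confluence_density_printed,wetland_area_km2,wetland_pct_printed,photic_pct_printed,density_reproducible
LSF,50,50,4.7,225.4,259.56,2,3,1.12,4.97,772000,772000,0.06,20.43,9.06,100,TRUE
LSL,26,26,6.5,136.31,151.51,3,3,0.62,4.55,148843,920843,0.13,6.85,5.03,60.32,FALSE
FR,104,104,4.3,131.6,253.24,4,2,0.71,5.4,319940,1240783,0.025,12.01,9.12,57.7,FALSE
LSP,35,35,15,241.02,315.58,8,5,0.75,3.11,21127,1261910,0.143,160.98,66.79,63.06,TRUE
FE,182,182,3.2,472.38,640.32,10,9,4.23,8.95,68245,1330155,0.049,29.99,6.35,28.38,TRUE
ETZ,58,58,22,1341.33,1521.37,2,1,14.96,11.15,2328,1332483,0.001,32.79,2.44,16.95,FALSE
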