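name,mean_c,disp_c,mean_w,disp_w,units
biasi_nmin,0.23,0.04,0.34,0.03,g NH4-N m-2 d-1
biasi_don,2.1,0.3,4.9,1.7,g m-2
chang_rootconc,14.7,0.5,10.7,1.2,g kg-1
chang_rootbiomass,890,114,1576,136,g m-2
chang_rootN,13.1,2.5,16.7,0.8,g m-2
rousk_fungal,23,1,27,0.7,nmol g-1
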