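camera,l_roi_px,u_l_roi_px,r_cam,u_r_cam,r_fov,u_r_fov,p_iso_um
canon,1802.4,0.473,6.186,0.618,6.404,0.619,6.897
topcon,1856.96,3.623,6.411,0.622,6.404,0.619,6.807
zeiss,2123.717,0.469,6.423,0.574,6.404,0.619,5.693
newvision,2090.61,0.068,6.478,0.647,6.404,0.619,6.050
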