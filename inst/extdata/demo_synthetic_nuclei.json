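[{"cell_id":"demo01","centroid":[0,0],"ellipse":{"cx":0,"cy":0,"a_um":8,"b_um":6,"theta_rad":0}},{"cell_id":"demo02","centroid":[0,0],"ellipse":{"cx":0,"cy":0,"a_um":7.5,"b_um":6.5,"theta_rad":0.3}}]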