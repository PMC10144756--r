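eye_id,al_mm,k_d,a_constant,iol_model,iol_power_d,postop_se_d,source
s001,27.44,38.34,118.4,SYN-A1,18.0,-0.50,clinic
s002,24.10,41.20,119.0,SYN-B2,21.5,-0.25,clinic
s003,30.25,35.10,118.4,SYN-A1,17.0,-1.25,clinic
s004,26.80,39.00,119.3,SYN-D4,19.5,0.25,clinic
s005,28.90,36.45,118.9,SYN-C3,18.5,-0.75,literature
s006,25.60,40.10,118.4,UNKNOWN,20.0,0.00,clinic
s007,33.10,33.80,119.0,SYN-B2,14.5,-1.50,clinic
s008,27.10,37.60,118.9,SYN-C3,19.0,-0.25,clinic
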