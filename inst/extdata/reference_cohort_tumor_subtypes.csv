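who_code,pixel_count
TAC-LG,6664074401
TAC-HG,4598290866
PCC-SRC,4244555130
PCC-NOS,2510671578
PAC-LG,1817583758
MAC,543032134
NEC,144753471
NDC,101471957
ACLS,69131679
MPAC,16310441
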