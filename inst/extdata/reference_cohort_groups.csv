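group,pixel_count
non_neoplastic,52490089929
invasive_carcinoma,20709875415
hg_dysplasia,620274997
lg_dysplasia,2501558821
unannotated,7754022436
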