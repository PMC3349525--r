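population_id,model,n_yellow,n_green,n_red,n_grey
diploid,disomic,2805,322,333,791
allotetraploid,disomic,1484,275,298,320
autotetraploid,tetrasomic,12707,1868,2216,3098
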