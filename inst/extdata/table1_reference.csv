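measure,mean,sd,cv_printed
repertoire_size,181,35,0.19
whistle_repertoire,28,5,0.18
whistle_occurrence,74,17,0.23
trill_repertoire,20,4,0.2
trill_occurrence,64,10,0.15
buzz_repertoire,5,1,0.33
buzz_occurrence,14,4,0.3
average_shortest_path,4.66,0.84,0.18
transitivity,0.18,0.03,0.17
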