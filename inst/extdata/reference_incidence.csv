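"band_start","band_end","incidence_per_100k"
45,49,16.4119692516557
50,54,38.5365330701778
55,59,78.9441776131966
60,64,144.311728735287
65,69,256.012832517891
70,74,410.978467622752
75,79,626.139296543639
80,84,805.223611874116
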