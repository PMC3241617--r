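"respondent_id","te1","te2","te3","conv1","conv2","conv3","idl1","idl2","idl3","mc1","mc2","use1","use2","use3","gs1","gs2","gs3","anchor","clinician_rating"
"s0002",3,3,3,2,2,2,1,1,1,4,3,0,0,1,3,3,2,4,"good"
"s0029",2,1,1,4,4,3,2,2,1,4,3,0,1,1,4,3,3,4,"acceptable"
"s0030",4,4,3,2,2,2,1,0,0,2,1,2,2,2,3,3,2,4,"excellent"
"s0038",3,3,2,1,0,0,3,3,2,4,3,0,0,0,4,3,3,4,"good"
"s0062",4,3,3,3,3,2,3,3,2,2,1,0,0,0,2,2,2,4,"excellent"
"s0063",2,1,1,2,1,1,2,2,1,4,3,1,2,2,3,2,2,4,"acceptable"
"s0082",4,4,4,3,3,2,1,1,0,3,3,2,2,2,3,2,2,5,"excellent"
"s0109",4,3,3,3,2,2,2,2,1,3,3,0,0,1,4,4,3,5,"good"
"s0113",4,4,3,2,2,2,1,1,0,4,4,0,0,1,4,4,4,5,"excellent"
"s0125",3,3,2,2,2,1,2,2,2,4,4,2,2,2,3,3,2,5,"good"
"s0135",2,1,1,4,3,3,3,3,3,4,3,2,2,2,4,3,3,5,"acceptable"
"s0189",2,2,2,4,3,3,3,2,2,4,3,0,0,1,2,1,1,5,"acceptable"
"s0195",4,4,4,4,4,4,4,4,3,3,2,1,1,1,3,3,2,5,"excellent"
"s0248",4,4,3,4,4,4,2,2,2,4,4,1,1,1,4,4,3,5,"excellent"
"s0257",3,3,3,4,4,4,2,2,1,4,4,0,0,0,4,3,3,3,"good"
"s0259",2,2,1,2,2,1,3,2,2,4,3,0,0,1,4,3,3,5,"acceptable"
"s0268",4,3,3,3,3,2,3,3,2,4,3,2,2,2,4,3,3,3,"good"
"s0269",4,4,3,4,3,3,1,1,1,4,4,0,0,0,3,2,2,3,"excellent"
"s0283",4,4,4,4,3,3,1,1,1,4,4,0,0,0,3,3,3,2,"excellent"
"s0287",3,3,3,4,4,3,4,4,4,3,2,0,0,0,4,3,3,6,"good"
"s0294",4,3,3,4,3,3,4,4,4,3,3,0,0,0,4,4,4,6,"good"
"s0345",4,4,4,4,4,4,2,1,1,4,4,0,1,1,4,4,4,6,"excellent"
"s0358",3,2,2,3,2,2,3,3,3,4,3,0,0,0,4,4,4,6,"good"
"s0385",4,4,3,4,4,3,4,4,3,3,2,0,0,0,4,4,4,6,"excellent"
"s0391",2,2,2,4,4,3,4,4,4,4,3,0,0,0,3,2,2,2,"acceptable"
"s0409",4,4,4,3,3,2,4,4,3,4,4,1,1,2,4,4,4,6,"excellent"
"s0422",3,2,2,3,3,3,3,3,3,3,2,0,0,0,4,4,3,7,"good"
"s0427",4,4,3,3,3,2,4,4,4,2,1,0,0,0,4,4,4,7,"excellent"
"s0433",3,3,3,4,3,3,3,3,3,4,4,0,0,0,3,3,3,7,"good"
"s0446",4,3,3,4,4,4,4,4,4,4,3,1,1,1,4,4,3,7,"excellent"
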