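"observationID","deploymentID","sequenceID","timestamp","observationType","scientificName","nImages","distances","isFirstTrigger"
"obs_1","d1","s1","2019-05-10T21:15:00Z","animal","Capreolus capreolus",12,"2.50;4.00",TRUE
"obs_2","d1","s2","2019-06-01T04:30:00Z","animal","Sus scrofa",3,"6.00",TRUE
"obs_3","d2","s3","2019-05-12T23:00:00Z","animal","Capreolus capreolus",7,"",TRUE
"obs_4","d3","s4","2019-05-20T02:10:00Z","blank","",1,"",TRUE
"obs_5","d3","s5","2019-07-04T22:45:00Z","unknown","",2,"",TRUE
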