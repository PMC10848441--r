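"deploymentID","locationID","longitude","latitude","start","end","sensitivity","cameraAngle"
"d1","L1",-8.201,42.001,"2019-05-07T08:00:00Z","2019-10-08T08:00:00Z","high",0.73
"d2","L2",-8.205,42.005,"2019-05-07T09:00:00Z","2019-10-08T09:00:00Z","high",0.73
"d3","L3",-8.209,42.009,"2019-05-08T08:00:00Z","2019-10-09T08:00:00Z","medium",0.73
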