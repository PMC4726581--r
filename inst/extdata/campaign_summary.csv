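day,data,max,min,range,mean,sd
Day1,Measured,4.939,2.242,2.698,3.476,0.602
Day1,BME,4.939,1.396,3.543,3.093,0.579
Day1,OK,4.490,2.320,2.170,3.133,0.422
Day1,Co-OK,4.460,2.240,2.220,3.120,0.496
Day2,Measured,6.649,3.635,3.014,5.810,0.512
Day2,BME,7.290,2.252,5.038,5.072,1.094
Day2,OK,6.650,3.610,3.040,5.530,0.616
Day2,Co-OK,6.540,3.410,3.130,5.537,0.620
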