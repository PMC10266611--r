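site,sex,age,risk
colon_synthetic,all,5,0
colon_synthetic,all,10,0
colon_synthetic,all,15,0
colon_synthetic,all,20,0
colon_synthetic,all,25,2e-04
colon_synthetic,all,30,0.0037
colon_synthetic,all,35,0.0158
colon_synthetic,all,40,0.0503
colon_synthetic,all,45,0.1245
colon_synthetic,all,50,0.2781
colon_synthetic,all,55,0.5041
colon_synthetic,all,60,0.8484
colon_synthetic,all,65,1.3291
colon_synthetic,all,70,1.9315
colon_synthetic,all,75,2.7349
colon_synthetic,all,80,3.7031
colon_synthetic,all,85,4.8645
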