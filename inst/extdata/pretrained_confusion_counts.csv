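"dataset","model","TP","TN","FP","FN","K"
"kaggle4","DenseNet201",9097,35317,2963,3663,4
"kaggle4","MobileNet",12360,37953,423,432,4
"kaggle4","MobileNetV2",7055,37792,608,5745,4
"kaggle4","MobileNetV3Small",5642,34055,4333,7154,4
"kaggle4","MobileNetV3Large",4307,36976,1424,8493,4
"kaggle4","VGG16",4317,36823,1577,8483,4
"kaggle4","VGG19",7258,33922,4478,5542,4
"kaggle4","Xception",6324,35897,2503,6476,4
"adni","DenseNet201",14057,29351,601,919,3
"adni","MobileNet",14348,29407,593,652,3
"adni","MobileNetV2",14187,29439,513,789,3
"adni","MobileNetV3Small",10680,27402,2598,4320,3
"adni","MobileNetV3Large",11019,28027,1973,3981,3
"adni","VGG16",11292,27944,2016,3688,3
"adni","VGG19",12350,28425,1495,2610,3
"adni","Xception",14365,29511,489,635,3
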