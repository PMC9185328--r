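"dataset","model","metric","printed","digits","scale"
"kaggle4","DenseNet201","precision",71.62,2,"percent"
"kaggle4","MobileNet","precision",96.69,2,"percent"
"kaggle4","MobileNetV2","precision",63.06,2,"percent"
"kaggle4","MobileNetV3Small","precision",56.68,2,"percent"
"kaggle4","MobileNetV3Large","precision",52.84,2,"percent"
"kaggle4","VGG16","precision",66.83,2,"percent"
"kaggle4","VGG19","precision",60.66,2,"percent"
"kaggle4","Xception","precision",71.19,2,"percent"
"kaggle4","DenseNet201","recall",71.29,2,"percent"
"kaggle4","MobileNet","recall",96.62,2,"percent"
"kaggle4","MobileNetV2","recall",55.12,2,"percent"
"kaggle4","MobileNetV3Small","recall",44.09,2,"percent"
"kaggle4","MobileNetV3Large","recall",33.65,2,"percent"
"kaggle4","VGG16","recall",33.73,2,"percent"
"kaggle4","VGG19","recall",56.7,2,"percent"
"kaggle4","Xception","recall",49.41,2,"percent"
"kaggle4","DenseNet201","specificity",92.26,2,"percent"
"kaggle4","MobileNet","specificity",98.9,2,"percent"
"kaggle4","MobileNetV2","specificity",98.42,2,"percent"
"kaggle4","MobileNetV3Small","specificity",88.71,2,"percent"
"kaggle4","MobileNetV3Large","specificity",96.29,2,"percent"
"kaggle4","VGG16","specificity",95.89,2,"percent"
"kaggle4","VGG19","specificity",88.34,2,"percent"
"kaggle4","Xception","specificity",93.48,2,"percent"
"kaggle4","DenseNet201","youden",63.55,2,"percent"
"kaggle4","MobileNet","youden",95.52,2,"percent"
"kaggle4","MobileNetV2","youden",53.53,2,"percent"
"kaggle4","MobileNetV3Small","youden",32.8,2,"percent"
"kaggle4","MobileNetV3Large","youden",29.94,2,"percent"
"kaggle4","VGG16","youden",29.62,2,"percent"
"kaggle4","VGG19","youden",45.04,2,"percent"
"kaggle4","Xception","youden",42.89,2,"percent"
"kaggle4","DenseNet201","mcc",63.11,2,"percent"
"kaggle4","MobileNet","mcc",95.54,2,"percent"
"kaggle4","MobileNetV2","mcc",54.89,2,"percent"
"kaggle4","MobileNetV3Small","mcc",35.85,2,"percent"
"kaggle4","MobileNetV3Large","mcc",34.92,2,"percent"
"kaggle4","VGG16","mcc",37.58,2,"percent"
"kaggle4","VGG19","mcc",45.86,2,"percent"
"kaggle4","Xception","mcc",48.89,2,"percent"
"kaggle4","DenseNet201","npv",90.96,2,"percent"
"kaggle4","MobileNet","npv",98.88,2,"percent"
"kaggle4","MobileNetV2","npv",88.19,2,"percent"
"kaggle4","MobileNetV3Small","npv",82.7,2,"percent"
"kaggle4","MobileNetV3Large","npv",81.98,2,"percent"
"kaggle4","VGG16","npv",81.58,2,"percent"
"kaggle4","VGG19","npv",86.11,2,"percent"
"kaggle4","Xception","npv",84.81,2,"percent"
"kaggle4","DenseNet201","fnr",0.287,3,"fraction"
"kaggle4","MobileNet","fnr",0.034,3,"fraction"
"kaggle4","MobileNetV2","fnr",0.449,3,"fraction"
"kaggle4","MobileNetV3Small","fnr",0.559,3,"fraction"
"kaggle4","MobileNetV3Large","fnr",0.664,3,"fraction"
"kaggle4","VGG16","fnr",0.663,3,"fraction"
"kaggle4","VGG19","fnr",0.433,3,"fraction"
"kaggle4","Xception","fnr",0.506,3,"fraction"
"kaggle4","DenseNet201","fdr",0.284,3,"fraction"
"kaggle4","MobileNet","fdr",0.033,3,"fraction"
"kaggle4","MobileNetV2","fdr",0.129,3,"fraction"
"kaggle4","MobileNetV3Small","fdr",0.433,3,"fraction"
"kaggle4","MobileNetV3Large","fdr",0.169,3,"fraction"
"kaggle4","VGG16","fdr",0.268,3,"fraction"
"kaggle4","VGG19","fdr",0.393,3,"fraction"
"kaggle4","Xception","fdr",0.288,3,"fraction"
"kaggle4","DenseNet201","fallout",0.077,3,"fraction"
"kaggle4","MobileNet","fallout",0.011,3,"fraction"
"kaggle4","MobileNetV2","fallout",0.016,3,"fraction"
"kaggle4","MobileNetV3Small","fallout",0.113,3,"fraction"
"kaggle4","MobileNetV3Large","fallout",0.037,3,"fraction"
"kaggle4","VGG16","fallout",0.041,3,"fraction"
"kaggle4","VGG19","fallout",0.117,3,"fraction"
"kaggle4","Xception","fallout",0.065,3,"fraction"
"adni","DenseNet201","precision",95.86,2,"percent"
"adni","MobileNet","precision",96.03,2,"percent"
"adni","MobileNetV2","precision",96.51,2,"percent"
"adni","MobileNetV3Small","precision",80.22,2,"percent"
"adni","MobileNetV3Large","precision",84.82,2,"percent"
"adni","VGG16","precision",84.84,2,"percent"
"adni","VGG19","precision",89.18,2,"percent"
"adni","Xception","precision",96.72,2,"percent"
"adni","DenseNet201","recall",93.86,2,"percent"
"adni","MobileNet","recall",95.65,2,"percent"
"adni","MobileNetV2","recall",94.73,2,"percent"
"adni","MobileNetV3Small","recall",71.2,2,"percent"
"adni","MobileNetV3Large","recall",73.46,2,"percent"
"adni","VGG16","recall",75.38,2,"percent"
"adni","VGG19","recall",82.55,2,"percent"
"adni","Xception","recall",95.77,2,"percent"
"adni","DenseNet201","specificity",97.99,2,"percent"
"adni","MobileNet","specificity",98.02,2,"percent"
"adni","MobileNetV2","specificity",98.29,2,"percent"
"adni","MobileNetV3Small","specificity",91.34,2,"percent"
"adni","MobileNetV3Large","specificity",93.42,2,"percent"
"adni","VGG16","specificity",93.27,2,"percent"
"adni","VGG19","specificity",95,2,"percent"
"adni","Xception","specificity",98.37,2,"percent"
"adni","DenseNet201","youden",91.86,2,"percent"
"adni","MobileNet","youden",93.68,2,"percent"
"adni","MobileNetV2","youden",93.02,2,"percent"
"adni","MobileNetV3Small","youden",62.54,2,"percent"
"adni","MobileNetV3Large","youden",66.88,2,"percent"
"adni","VGG16","youden",68.65,2,"percent"
"adni","VGG19","youden",77.56,2,"percent"
"adni","Xception","youden",94.14,2,"percent"
"adni","DenseNet201","mcc",92.36,2,"percent"
"adni","MobileNet","mcc",93.77,2,"percent"
"adni","MobileNetV2","mcc",93.47,2,"percent"
"adni","MobileNetV3Small","mcc",64.59,2,"percent"
"adni","MobileNetV3Large","mcc",69.6,2,"percent"
"adni","VGG16","mcc",70.91,2,"percent"
"adni","VGG19","mcc",79.17,2,"percent"
"adni","Xception","mcc",97.91,2,"percent"
"adni","DenseNet201","npv",97.02,2,"percent"
"adni","MobileNet","npv",97.84,2,"percent"
"adni","MobileNetV2","npv",97.42,2,"percent"
"adni","MobileNetV3Small","npv",86.62,2,"percent"
"adni","MobileNetV3Large","npv",87.94,2,"percent"
"adni","VGG16","npv",88.5,2,"percent"
"adni","VGG19","npv",91.68,2,"percent"
"adni","Xception","npv",97.91,2,"percent"
"adni","DenseNet201","fnr",0.061,3,"fraction"
"adni","MobileNet","fnr",0.043,3,"fraction"
"adni","MobileNetV2","fnr",0.053,3,"fraction"
"adni","MobileNetV3Small","fnr",0.288,3,"fraction"
"adni","MobileNetV3Large","fnr",0.265,3,"fraction"
"adni","VGG16","fnr",0.246,3,"fraction"
"adni","VGG19","fnr",0.174,3,"fraction"
"adni","Xception","fnr",0.042,3,"fraction"
"adni","DenseNet201","fdr",0.041,3,"fraction"
"adni","MobileNet","fdr",0.04,3,"fraction"
"adni","MobileNetV2","fdr",0.035,3,"fraction"
"adni","MobileNetV3Small","fdr",0.198,3,"fraction"
"adni","MobileNetV3Large","fdr",0.152,3,"fraction"
"adni","VGG16","fdr",0.152,3,"fraction"
"adni","VGG19","fdr",0.108,3,"fraction"
"adni","Xception","fdr",0.033,3,"fraction"
"adni","DenseNet201","fallout",0.02,3,"fraction"
"adni","MobileNet","fallout",0.02,3,"fraction"
"adni","MobileNetV2","fallout",0.017,3,"fraction"
"adni","MobileNetV3Small","fallout",0.087,3,"fraction"
"adni","MobileNetV3Large","fallout",0.066,3,"fraction"
"adni","VGG16","fallout",0.067,3,"fraction"
"adni","VGG19","fallout",0.05,3,"fraction"
"adni","Xception","fallout",0.016,3,"fraction"
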