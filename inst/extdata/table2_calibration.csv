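isup,ageMean,ageSd,psaMedian,psaQ1,psaQ3,psadMedian,psadQ1,psadQ3,infMedian,infQ1,infQ3,visibilityProb,zonePZ,zoneTZ,zoneAS,diamMedian,diamQ1,diamQ3,crossZonalProb,ct3Prob,highBProb,adcRsMedian,adcRsQ1,adcRsQ3,adcSsMedian,adcSsQ1,adcSsQ3
1,65,9,7.0,5.3,9.5,0.16,0.11,0.22,15,5,40,0.80,0.78,0.14,0.08,12,10,14,0.10,0.05,0.60,978,793,1141,747,599,873
2,67,9,9.0,6.4,12.8,0.23,0.13,0.37,60,35,80,0.94,0.70,0.18,0.12,14,13,18,0.32,0.09,0.74,959,848,1024,714,652,849
3,70,8,8.0,6.3,11.1,0.20,0.13,0.30,50,25,80,0.98,0.78,0.18,0.04,14,12,16,0.44,0.18,0.84,770,707,932,691,495,788
4,71,8,11.6,6.6,15.2,0.26,0.20,0.41,60,25,80,1.00,0.78,0.14,0.08,14,11,18,0.60,0.38,0.90,704,608,824,684,581,798
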