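altitude,slope,aspect,phenology,organic_carbon,total_nitrogen,phosphorus,potassium,sand,silt,clay,ec,ph
2803.15,5.77214,3,3,0.538119,0.527064,2.31365,270.583,37.6659,46.7295,11.3981,0.0822971,7.21255
2427.81,22.8156,3,2,1.6232,0.376626,4.87173,189.792,48.7719,42.1544,25.9994,0.123908,6.59009
1436.74,14.5685,3,1,0.636965,0.513639,3.36633,248.236,45.9011,42.9029,17.8915,0.0521651,7.39547
1776.64,26.3132,3,2,0.645804,0.466354,2.94161,267.786,49.0122,34.628,10.0487,0.0752179,7.65896
2424.88,12.7324,3,1,0.117148,0.346707,2.724,149.711,37.5065,35.7279,12.9412,0.0601919,7.17614
1163.79,16.9996,3,2,0.0496229,0.401218,1.20533,234.104,49.387,35.6868,13.066,0.0413993,6.39553
2204.56,20.217,3,2,1.87453,0.409056,3.61821,247.409,43.8791,43.4264,22.4862,0.0935739,7.11627
3294.9,5.1706,3,2,0.423124,0.168026,2.97849,219.13,48.2659,36.101,21.2398,0.0569304,7.24198
1699.13,16.2898,3,1,0.776458,0.513211,3.39074,153.86,38.8747,41.139,14.8597,0.0590659,6.33642
2489.5,6.90075,2,2,0.338131,0.251414,3.74659,273.629,39.0608,36.2476,20.938,0.113271,7.15886
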