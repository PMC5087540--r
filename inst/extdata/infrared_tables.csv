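table,image,method,precision,recall,f1
1,plane,GVF,0.9475,0.9246,0.9359
1,plane,GGVF,0.8958,0.9759,0.9341
1,plane,NGVF,0.7723,0.9407,0.8482
1,plane,NBGVF,0.8984,0.9688,0.9323
1,plane,CN-GGVF,0.914,0.9618,0.9373
1,plane,LIF,0.955,0.3628,0.5259
1,plane,SOAC,0.9948,0.3829,0.553
1,plane,Proposed,0.9484,0.9427,0.9456
1,ship,GVF,0.9398,0.8645,0.9006
1,ship,GGVF,0.9497,0.9453,0.9475
1,ship,NGVF,0.9859,0.8858,0.9332
1,ship,NBGVF,0.9835,0.8331,0.9021
1,ship,CN-GGVF,0.9494,0.9399,0.9446
1,ship,LIF,0.9961,0.3391,0.506
1,ship,SOAC,0.9269,0.9399,0.9334
1,ship,Proposed,0.9597,0.9386,0.949
1,tank,GVF,0.925,0.8621,0.8924
1,tank,GGVF,0.8972,0.9549,0.9251
1,tank,NGVF,0.8993,0.9116,0.9054
1,tank,NBGVF,0.8929,0.8868,0.8899
1,tank,CN-GGVF,0.8846,0.9295,0.9065
1,tank,LIF,0.8625,0.7073,0.7772
1,tank,SOAC,0.6616,0.3389,0.4482
1,tank,Proposed,0.9122,0.9505,0.931
2,planeN,GVF,0.9177,0.9296,0.9236
2,planeN,GGVF,0.7606,0.9899,0.8603
2,planeN,NGVF,0.8643,0.9668,0.9127
2,planeN,NBGVF,0.8705,0.9859,0.9246
2,planeN,CN-GGVF,0.7147,0.996,0.8322
2,planeN,SOAC,0.9337,0.4814,0.6353
2,planeN,LIF,0.9769,0.3819,0.5491
2,planeN,Proposed,0.8861,0.9849,0.9329
2,shipN,GVF,0.9756,0.8284,0.896
2,shipN,GGVF,0.9097,0.9753,0.9414
2,shipN,NGVF,0.9262,0.9045,0.9152
2,shipN,NBGVF,0.944,0.8963,0.9195
2,shipN,CN-GGVF,0.8767,0.9733,0.9225
2,shipN,SOAC,0.9798,0.9045,0.9406
2,shipN,LIF,0.9555,0.4159,0.5795
2,shipN,Proposed,0.9527,0.9406,0.9466
2,tankN,GVF,0.9381,0.8528,0.8934
2,tankN,GGVF,0.8944,0.9431,0.9181
2,tankN,NGVF,0.9145,0.9196,0.9171
2,tankN,NBGVF,0.9027,0.8893,0.896
2,tankN,CN-GGVF,0.8607,0.9518,0.904
2,tankN,SOAC,0.9407,0.3432,0.5029
2,tankN,LIF,0.9104,0.7168,0.8021
2,tankN,Proposed,0.8815,0.9567,0.9176
3,planeN2,GVF,0.6992,0.8714,0.7758
3,planeN2,GGVF,0.8713,0.9869,0.9255
3,planeN2,NGVF,0.6366,0.9477,0.7616
3,planeN2,NBGVF,0.9076,0.793,0.8464
3,planeN2,CN-GGVF,0.8928,0.9789,0.9338
3,planeN2,SOAC,0.7794,0.5327,0.6328
3,planeN2,LIF,0.978,0.3568,0.5228
3,planeN2,Proposed,0.9026,0.9869,0.9429
3,shipN2,GVF,0.9805,0.8336,0.9011
3,shipN2,GGVF,0.9455,0.9317,0.9385
3,shipN2,NGVF,0.987,0.7533,0.8545
3,shipN2,NBGVF,0.9598,0.8223,0.8857
3,shipN2,CN-GGVF,0.8277,0.9662,0.8887
3,shipN2,SOAC,0.9852,0.884,0.9318
3,shipN2,LIF,0.9711,0.3342,0.4973
3,shipN2,Proposed,0.9277,0.9443,0.9359
3,tankN2,GVF,0.9487,0.8002,0.8682
3,tankN2,GGVF,0.8297,0.9307,0.8773
3,tankN2,NGVF,0.8835,0.8955,0.8894
3,tankN2,NBGVF,0.9383,0.8565,0.8956
3,tankN2,CN-GGVF,0.8086,0.9326,0.8662
3,tankN2,SOAC,0.6616,0.3389,0.4482
3,tankN2,LIF,0.9082,0.7038,0.793
3,tankN2,Proposed,0.9037,0.9338,0.9185
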