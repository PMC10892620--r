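compound_id,pic50,logp,mw,logs,mr,mv,pol,e_homo,e_lumo,e_total,hba,hbd,q_s,q_n,q_c1,q_c2,q_c3,clsc,tindx,bindx
6a,4.526,1.725,251.257,-3.55,68.34,679.733,24.44,-2.406,-6.114,-32074.5,4,2,-0.371,-0.267,0.044,-0.116,0.643,17,3549,106143
6b,4.947,2.487,330.153,-4.26,75.874,735.382,27.066,-2.585,-6.254,-102106,4,2,-0.373,-0.26,0.046,-0.223,0.799,18,3884,136497
6c,4.848,2.790,344.18,-4.38,80.643,782.485,28.901,-2.521,-6.137,-103175,4,1,0.412,-0.262,0.083,-0.079,0.596,19,4627,177387
6d,5.092,3.346,370.218,-5.04,89.806,877.383,32.379,-2.653,-6.337,-105282,4,1,-0.03,-0.207,0.015,-0.228,0.62,21,6539,295568
6e,5.276,4.127,398.271,-5.93,99.761,962.68,36.049,-2.604,-6.276,-107422,4,1,-0.011,-0.207,0.008,-0.231,0.624,23,8921,472150
6f,5.310,3.961,386.26,-5.67,94.516,947.696,34.406,-2.673,-6.319,-106385,4,1,-0.17,-0.238,0.01,-0.18,0.589,22,7722,377714
6g,5.119,4.361,420.277,-5.92,109.394,978.128,38.561,-2.607,-6.272,-109464,4,1,-0.191,0.239,-0.016,-0.274,0.628,25,11391,546426
7a,4.652,3.132,358.207,-4.38,85.54,819.806,30.736,-2.428,-6.060,-104245,4,0,0.166,0.032,0.082,-0.18,0.529,20,5375,224427
7b,5.092,4.703,434.304,-5.94,114.291,1024.088,40.396,-2.512,-6.199,-110534,4,0,-0.07,0.056,-0.047,-0.338,0.675,26,12739,653163
7c,5.086,4.469,412.298,-5.94,104.658,1030.626,37.884,-2.509,-6.201,-108492,4,0,-0.07,0.056,-0.015,-0.295,0.542,24,10061,573023
7d,4.770,5.025,438.336,-5.94,113.821,1083.626,41.362,-2.486,-6.167,-110599,4,0,-0.07,0.34,-0.034,-0.07,0.315,26,12885,843380
7e(ref),5.337,5.247,440.352,-6.77,113.824,1107.71,41.554,-2.465,-6.149,-110632,4,0,-0.231,0.412,-0.031,0.104,0.162,26,12715,833233
7f,4.910,5.639,454.379,-7.23,118.531,1151.608,43.389,-2.476,-6.166,-111703,4,0,-0.073,0.391,-0.038,0.157,-0.092,27,14584,1020188
7g,5.000,5.805,466.39,-7.49,123.776,1190.101,45.032,-2.443,-6.144,-112739,4,0,-0.129,0.378,-0.021,0.032,0.149,28,16299,1217684
7h,4.987,6.039,47.544,-7.49,133.409,1195.143,47.544,-2.504,-6.185,-114781,4,0,-0.17,0.418,0.019,0.178,-0.107,30,19801,1300406
7i,4.917,4.303,400.287,-5.68,99.413,999.466,36.241,-2.525,-6.227,-107456,4,0,-0.067,0.057,0.002,-0.289,0.554,23,8758,462362
7j,5.102,4.859,426.325,-6.35,108.576,1054.01,39.719,-2.515,-6.191,-109562,4,0,-0.107,0.322,-0.012,-0.01,0.279,25,11350,692217
7k,5.013,5.081,428.341,-6.51,108.579,1077.561,39.911,-2.481,-6.174,-109596,4,0,-0.235,0.411,-0.013,0.106,0.18,25,11188,683230
7m,5.180,5.873,476.385,-7.23,128.164,1165.816,45.901,-2.517,-6.033,-113744,4,0,-0.201,0.383,0.029,0.281,-0.302,29,17754,1097466
12,4.914,3.653,375.439,-5.86,104.67,1029.891,38.791,-2.272,-5.889,-42615.8,5,1,-0.324,-0.253,0.036,-0.366,0.871,26,12024,614951
13d,4.644,5.332,443.558,-7.42,128.685,1274.358,47.774,-2.127,-5.772,-47932.8,5,0,-0.167,0.364,-0.041,-0.069,0.435,31,20797,1445876
13e,4.686,5.166,431.547,-7.16,123.44,1242.555,46.131,-2.154,-5.791,-46896.2,5,0,-0.118,0.368,-0.046,0.104,0.183,30,18773,1230606
14b,5.194,3.574,333.402,-5.49,95.931,938.266,35.258,-2.229,-5.880,-38451.7,4,1,-0.348,0.369,0.027,0.227,0.096,23,8545,435114
14d,4.921,4.132,359.44,-6.22,105.883,1015.594,38.736,-2.212,-5.880,-40568.2,4,1,-0.209,0.338,-0.02,0.157,0.033,25,11390,672700
14e,5.018,3.966,347.429,-5.97,100.638,982.053,37.093,-2.237,-5.901,-39531.6,4,1,-0.157,0.356,-0.041,0.293,-0.25,24,10034,55093
14f,5.143,4.366,381.446,-6.22,115.516,1025.745,41.248,-2.269,-5.927,-42610.1,4,1,-0.22,0.399,0.019,0.301,-0.202,27,14174,750061
14g,4.533,2.453,291.321,-4.66,81.868,797.075,29.753,-2.363,-6.008,-35251.2,4,2,-0.312,0.268,0.043,-0.166,0.521,20,5681,226445
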