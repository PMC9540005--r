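sigma_mpa,temp_c,rho_gcc,cycles_to_failure
40,21,1.7,1572012900
60,21,1.7,10302070
80,21,1.7,290860.11
100,21,1.7,18281.002
120,21,1.7,1906.1301
40,37,1.7,809946080
60,37,1.7,5307921.5
80,37,1.7,149859.46
100,37,1.7,9418.896
120,37,1.7,982.09285
40,21,1.85,4747403100
60,21,1.85,31111754
80,21,1.85,878383.48
100,21,1.85,55207.744
120,21,1.85,5756.421
40,37,1.85,2445998100
60,37,1.85,16029667
80,37,1.85,452568.33
100,37,1.85,28444.611
120,37,1.85,2965.873
40,21,2,14336928000
60,21,2,93955995
80,21,2,2652675.7
100,21,2,166724.72
120,21,2,17384.114
40,37,2,7386796000
60,37,2,48408820
80,37,2,1366734.5
100,37,2,85901.352
120,37,2,8956.7932
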