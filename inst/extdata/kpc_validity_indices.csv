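dataset,cluster_set,index,value
128x128,8,xie_beni,210.566
128x128,9,xie_beni,123.37128
128x128,10,xie_beni,269.10936
128x128,11,xie_beni,109.27157
128x128,12,xie_beni,197.86335
128x128,13,xie_beni,83.87588
128x128,14,xie_beni,77.13336
128x128,15,xie_beni,89.88902
128x128,16,xie_beni,88.22176
128x128,17,xie_beni,107.32371
128x128,18,xie_beni,130.49625
128x128,8,calinski_harabasz,3417.12372
128x128,9,calinski_harabasz,3068.88135
128x128,10,calinski_harabasz,1854.72219
128x128,11,calinski_harabasz,3268.10641
128x128,12,calinski_harabasz,2415.86019
128x128,13,calinski_harabasz,3405.33049
128x128,14,calinski_harabasz,3458.73942
128x128,15,calinski_harabasz,3335.13698
128x128,16,calinski_harabasz,2616.69806
128x128,17,calinski_harabasz,2582.27002
128x128,18,calinski_harabasz,2536.53023
128x128,8,c_index,0.11338
128x128,9,c_index,0.1175
128x128,10,c_index,0.10734
128x128,11,c_index,0.10647
128x128,12,c_index,0.11046
128x128,13,c_index,0.09428
128x128,14,c_index,0.08816
128x128,15,c_index,0.09366
128x128,16,c_index,0.10316
128x128,17,c_index,0.08943
128x128,18,c_index,0.09558
128x128,8,hartigan,0.46719
128x128,9,hartigan,0.4933
128x128,10,hartigan,0.10758
128x128,11,hartigan,0.77948
128x128,12,hartigan,0.5727
128x128,13,hartigan,1.00307
128x128,14,hartigan,1.09874
128x128,15,hartigan,1.13652
128x128,16,hartigan,0.96298
128x128,17,hartigan,1.01434
128x128,18,hartigan,1.05716
128x128,8,dunn,0.00697
128x128,9,dunn,0.01016
128x128,10,dunn,0.00727
128x128,11,dunn,0.00763
128x128,12,dunn,0.00592
128x128,13,dunn,0.0136
128x128,14,dunn,0.01128
128x128,15,dunn,0.0106
128x128,16,dunn,0.01104
128x128,17,dunn,0.00704
128x128,18,dunn,0.00981
128x128,8,mclain_rao,0.49971
128x128,9,mclain_rao,0.49636
128x128,10,mclain_rao,0.51922
128x128,11,mclain_rao,0.45388
128x128,12,mclain_rao,0.47768
128x128,13,mclain_rao,0.42899
128x128,14,mclain_rao,0.43028
128x128,15,mclain_rao,0.42482
128x128,16,mclain_rao,0.44847
128x128,17,mclain_rao,0.42538
128x128,18,mclain_rao,0.42538
64x64,8,xie_beni,208.66015
64x64,9,xie_beni,94.03908
64x64,10,xie_beni,99.14787
64x64,11,xie_beni,85.44762
64x64,12,xie_beni,108.40803
64x64,13,xie_beni,76.72227
64x64,14,xie_beni,91.36067
64x64,15,xie_beni,164.86141
64x64,16,xie_beni,113.37091
64x64,17,xie_beni,740.29343
64x64,18,xie_beni,182.85043
64x64,8,calinski_harabasz,1556.83725
64x64,9,calinski_harabasz,2684.95843
64x64,10,calinski_harabasz,2934.73878
64x64,11,calinski_harabasz,3297.3707
64x64,12,calinski_harabasz,2784.5543
64x64,13,calinski_harabasz,2862.23775
64x64,14,calinski_harabasz,2692.61013
64x64,15,calinski_harabasz,2097.78152
64x64,16,calinski_harabasz,2320.9412
64x64,17,calinski_harabasz,1267.71892
64x64,18,calinski_harabasz,1317.30883
64x64,8,c_index,0.11185
64x64,9,c_index,0.11189
64x64,10,c_index,0.09697
64x64,11,c_index,0.08767
64x64,12,c_index,0.08885
64x64,13,c_index,0.08772
64x64,14,c_index,0.08332
64x64,15,c_index,0.10025
64x64,16,c_index,0.07896
64x64,17,c_index,0.07132
64x64,18,c_index,0.07615
64x64,8,hartigan,-0.31895
64x64,9,hartigan,0.35966
64x64,10,hartigan,0.56646
64x64,11,hartigan,0.78839
64x64,12,hartigan,0.71473
64x64,13,hartigan,0.82933
64x64,14,hartigan,0.84834
64x64,15,hartigan,0.67289
64x64,16,hartigan,0.84304
64x64,17,hartigan,0.30289
64x64,18,hartigan,0.40195
64x64,8,dunn,0.00734
64x64,9,dunn,0.01075
64x64,10,dunn,0.00873
64x64,11,dunn,0.01132
64x64,12,dunn,0.00957
64x64,13,dunn,0.01146
64x64,14,dunn,0.01307
64x64,15,dunn,0.0067
64x64,16,dunn,0.0106
64x64,17,dunn,0.00335
64x64,18,dunn,0.00674
64x64,8,mclain_rao,0.52964
64x64,9,mclain_rao,0.49275
64x64,10,mclain_rao,0.45613
64x64,11,mclain_rao,0.44574
64x64,12,mclain_rao,0.44275
64x64,13,mclain_rao,0.44423
64x64,14,mclain_rao,0.43151
64x64,15,mclain_rao,0.46676
64x64,16,mclain_rao,0.43344
64x64,17,mclain_rao,0.45157
64x64,18,mclain_rao,0.46498
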