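-0.57215235 0.7352895 0.36330571
0.16093157 -0.62878737 0.7607414
-0.08612638 -0.92564388 0.36846391
0.82449456 0.38772517 0.41216248
-0.89425024 0.38582714 0.22683457
0.54213299 0.30162569 0.78429189
-0.29617924 0.18506265 0.93703238
-0.51946571 -0.80997969 0.27219162
-0.25405145 0.96516694 0.06253505
-0.35273393 0.59466853 0.72245977
-0.91602825 -0.05709515 0.39702946
-0.05305726 0.87393841 0.48313205
0.80113282 -0.04944728 0.59644042
-0.56576069 -0.1630465 0.80828874
-0.31047874 -0.63936206 0.7034338
0.90252702 -0.3531845 0.24638524
0.15995165 0.1016954 0.98187245
0.62424551 -0.52601055 0.57760752
0.68024875 -0.7283295 0.08244861
0.09557187 0.53957364 0.83649645
0.63477225 0.75250764 0.17548914
0.43247043 -0.23071079 0.87163172
-0.88367361 -0.45977654 0.08790046
-0.71362037 -0.46770792 0.52153165
-0.1092067 -0.28779286 0.95144583
-0.70439991 0.28451313 0.6502869
0.41127015 0.72110445 0.5575529
0.99446663 0.05222876 0.09114981
0.35106984 -0.85221574 0.38791532
0.2189474 0.96998807 0.10576002
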