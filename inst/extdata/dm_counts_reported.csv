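timepoint,mode,direction,count
3d,negative,HFHS_vs_CTRL,0
3d,negative,CTRL_vs_HFHS,10
3d,positive,HFHS_vs_CTRL,0
3d,positive,CTRL_vs_HFHS,1
1w,negative,HFHS_vs_CTRL,28
1w,negative,CTRL_vs_HFHS,12
1w,positive,HFHS_vs_CTRL,1
1w,positive,CTRL_vs_HFHS,33
4w,negative,HFHS_vs_CTRL,5
4w,negative,CTRL_vs_HFHS,39
4w,positive,HFHS_vs_CTRL,17
4w,positive,CTRL_vs_HFHS,16
8w,negative,HFHS_vs_CTRL,23
8w,negative,CTRL_vs_HFHS,21
8w,positive,HFHS_vs_CTRL,24
8w,positive,CTRL_vs_HFHS,29
12w,negative,HFHS_vs_CTRL,37
12w,negative,CTRL_vs_HFHS,18
12w,positive,HFHS_vs_CTRL,7
12w,positive,CTRL_vs_HFHS,2
16w,negative,HFHS_vs_CTRL,27
16w,negative,CTRL_vs_HFHS,83
16w,positive,HFHS_vs_CTRL,18
16w,positive,CTRL_vs_HFHS,99
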