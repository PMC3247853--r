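antibody_id,gene,fam,env,cv,iv,exp
HPA001886,il12a,42.1,20.1,0,0,37.8
HPA003412,plat,36.9,17,0,8.4,37.7
HPA002550,ttr,31.3,0.7,0,18,49.9
HPA001816,serpinc1,31,0,2.4,0,66.7
HPA006279,adamtsl4,29.7,27,0,0,43.3
HPA002265,a2m,27.9,3,0,20.6,48.5
HPA002549,apoa4,27.4,0,2.2,25.1,45.4
HPA000440,ptprc,26.4,0,0,0,73.6
HPA001817,cfb,26.3,6.4,0,4.2,63.1
HPA007875,mmp3,25.6,0,8,0,66.4
HPA002891,akt1,25.6,0,0,0,74.4
HPA004063,aip,25.5,0,0,8.3,66.1
HPA003732,apoh,25.5,0,4.5,0,70
HPA001352,apoa4,25.2,0,3,31.7,40.2
HPA001610,pon1,24.5,0,0,12.2,63.3
HPA002350,c1qa,24,0,0,9.8,66.2
HPA001249,ikbkb,22.5,0.7,0,24,52.8
HPA001832,cfb,22.5,0,0,19,58.6
HPA005692,tf,22.4,9.1,5,0,63.5
HPA000951,cfb,21.6,19.8,8.2,0,50.5
HPA000952,cfb,21.4,11.9,0.2,9.1,57.4
HPA001900,fgb,20.6,0.5,0,15.8,63.1
HPA001885,serpinf2,20.6,1.4,0,22,56
HPA001247,cyc1,18.8,26.7,0,3.7,50.7
HPA008255,slc27a1,18.5,2.5,0,10.6,68.4
HPA001465,c7,17.9,0,13.2,14.1,54.9
HPA000428,renbp,16.9,17.2,0,9.9,56
HPA009656,znf174,16.1,20.2,0.5,24.3,38.9
HPA004061,c17orf75,15.3,9.8,20.3,0,54.7
HPA007845,casq1,13.9,0,0,0,86.1
HPA006514,jtb,13.6,19.9,0,0,66.5
HPA004732,cpn2,12.9,0,0,0,87.1
HPA001654,apoh,12.2,0,1,5.2,81.6
HPA003020,sparc,11.9,5.6,12.3,34.5,35.5
HPA004716,kif2a,11.3,0,0,0,88.7
HPA004335,acpp,11.3,0,0,0,88.7
HPA002989,sparc,10.9,26.5,0,3.1,59.5
HPA000834,g6pd,10.1,30.9,0,19.1,39.9
HPA001834,cp,9.9,22.4,0,0,67.7
HPA001252,foxo1,7.8,22.2,3.2,0,66.9
HPA008354,ppbp,7.6,9.2,8.5,7.3,67.4
HPA003980,il18,7.3,5.1,17.2,34.4,36
HPA004252,cd4,6.7,3.2,6.6,15.6,67.9
HPA001901,fgb,6.3,7.9,0,19.2,66.6
HPA001527,tf,5.9,8.6,8.9,0,76.7
HPA008257,tgfbr3,3.6,49.2,2.1,0,45.1
HPA006493,me1,2.9,1.4,21.2,5.5,69.1
HPA007724,pros1,1.3,21.8,0,20.7,56.2
HPA004877,icam1,1.3,27.1,0,0,71.6
HPA001254,ckb,1.1,21.1,6.5,29.6,41.7
HPA001560,bche,0.9,30.3,8.8,0,60.1
HPA003825,f12,0.5,0,1.6,21.9,76
HPA004824,h6pd,0.1,9.4,0,0,90.6
HPA000793,eno3,0,19.8,2.7,27.8,49.7
HPA005448,rad17,0,2.1,3.9,0,93.9
HPA010525,gpr1,0,11.9,8.3,0,79.9
HPA000288,ace2,0,58.9,2.7,6.9,31.5
HPA007838,pogk,0,0,0,31.8,68.2
HPA001804,f13a,0,39.1,0,0,60.9
HPA001833,ltf,0,21.6,0,0,78.4
HPA004146,cpb2,0,0,0,0,100
HPA000572,apoj,0,38.9,0,8.6,52.5
HPA004056,lamb1,0,0,0,40.1,59.9
HPA004796,tnfrsf1b,0,9.4,0,6.7,83.9
HPA004827,usp13,0,0,0,0,100
HPA003827,f13b,0,16.7,8.6,0,74.7
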