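cell_line,group,day,column,mean_pct,sem_pct,n
U87,treated,4,A,82.6,2.5,5
U87,treated,4,B,78.6,2.3,5
U87,treated,4,G,85.6,2.5,5
U87,treated,7,A,63.3,3.1,5
U87,treated,7,B,58.9,3.7,5
U87,treated,7,G,70.6,4.4,5
LN229,treated,4,A,63.3,2.6,5
LN229,treated,4,B,52.6,4.4,5
LN229,treated,4,C,51.7,7.0,5
LN229,treated,4,G,65.5,5.0,5
LN229,treated,7,A,55.4,2.5,5
LN229,treated,7,B,43.4,3.2,5
LN229,treated,7,C,43.0,6.1,5
LN229,treated,7,D,41.4,7.4,5
LN229,treated,7,G,66.1,3.5,5
PDX,treated,7,A,20.8,2.1,5
PDX,treated,7,C,15.0,4.7,5
PDX,treated,7,G,25.1,2.3,5
PDX,control,7,ALL,70.5,NA,3
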