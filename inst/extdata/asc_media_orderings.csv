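stratum,algorithm,gene,position
FBS,delta_ct,EF1A,1
FBS,delta_ct,TBP,2
FBS,delta_ct,RPLP0,3
FBS,delta_ct,ACTB,4
FBS,delta_ct,GAPDH,5
FBS,bestkeeper,TBP,1
FBS,bestkeeper,EF1A,2
FBS,bestkeeper,RPLP0,3
FBS,bestkeeper,GAPDH,4
FBS,bestkeeper,ACTB,5
FBS,normfinder,EF1A,1
FBS,normfinder,TBP,2
FBS,normfinder,RPLP0,3
FBS,normfinder,ACTB,4
FBS,normfinder,GAPDH,5
FBS,genorm,EF1A,1
FBS,genorm,RPLP0,1
FBS,genorm,TBP,2
FBS,genorm,ACTB,3
FBS,genorm,GAPDH,4
X1,delta_ct,GAPDH,1
X1,delta_ct,TBP,2
X1,delta_ct,ACTB,3
X1,delta_ct,EF1A,4
X1,delta_ct,RPLP0,5
X1,bestkeeper,GAPDH,1
X1,bestkeeper,ACTB,2
X1,bestkeeper,TBP,3
X1,bestkeeper,EF1A,4
X1,bestkeeper,RPLP0,5
X1,normfinder,GAPDH,1
X1,normfinder,TBP,2
X1,normfinder,ACTB,3
X1,normfinder,EF1A,4
X1,normfinder,RPLP0,5
X1,genorm,TBP,1
X1,genorm,GAPDH,1
X1,genorm,ACTB,2
X1,genorm,EF1A,3
X1,genorm,RPLP0,4
X2,delta_ct,GAPDH,1
X2,delta_ct,TBP,2
X2,delta_ct,ACTB,3
X2,delta_ct,RPLP0,4
X2,delta_ct,EF1A,5
X2,bestkeeper,TBP,1
X2,bestkeeper,ACTB,2
X2,bestkeeper,GAPDH,3
X2,bestkeeper,RPLP0,4
X2,bestkeeper,EF1A,5
X2,normfinder,GAPDH,1
X2,normfinder,TBP,2
X2,normfinder,ACTB,3
X2,normfinder,RPLP0,4
X2,normfinder,EF1A,5
X2,genorm,RPLP0,1
X2,genorm,GAPDH,1
X2,genorm,ACTB,2
X2,genorm,TBP,3
X2,genorm,EF1A,4
X1/X2,delta_ct,GAPDH,1
X1/X2,delta_ct,TBP,2
X1/X2,delta_ct,ACTB,3
X1/X2,delta_ct,EF1A,4
X1/X2,delta_ct,RPLP0,5
X1/X2,bestkeeper,GAPDH,1
X1/X2,bestkeeper,TBP,2
X1/X2,bestkeeper,ACTB,3
X1/X2,bestkeeper,RPLP0,4
X1/X2,bestkeeper,EF1A,5
X1/X2,normfinder,GAPDH,1
X1/X2,normfinder,TBP,2
X1/X2,normfinder,ACTB,3
X1/X2,normfinder,EF1A,4
X1/X2,normfinder,RPLP0,5
X1/X2,genorm,TBP,1
X1/X2,genorm,GAPDH,1
X1/X2,genorm,ACTB,2
X1/X2,genorm,EF1A,3
X1/X2,genorm,RPLP0,4
FBS/X1,delta_ct,EF1A,1
FBS/X1,delta_ct,TBP,2
FBS/X1,delta_ct,GAPDH,3
FBS/X1,delta_ct,RPLP0,4
FBS/X1,delta_ct,ACTB,5
FBS/X1,bestkeeper,TBP,1
FBS/X1,bestkeeper,GAPDH,2
FBS/X1,bestkeeper,EF1A,3
FBS/X1,bestkeeper,RPLP0,4
FBS/X1,bestkeeper,ACTB,5
FBS/X1,normfinder,EF1A,1
FBS/X1,normfinder,TBP,2
FBS/X1,normfinder,GAPDH,3
FBS/X1,normfinder,RPLP0,4
FBS/X1,normfinder,ACTB,5
FBS/X1,genorm,EF1A,1
FBS/X1,genorm,TBP,1
FBS/X1,genorm,GAPDH,2
FBS/X1,genorm,RPLP0,3
FBS/X1,genorm,ACTB,4
FBS/X2,delta_ct,TBP,1
FBS/X2,delta_ct,EF1A,2
FBS/X2,delta_ct,RPLP0,3
FBS/X2,delta_ct,GAPDH,4
FBS/X2,delta_ct,ACTB,5
FBS/X2,bestkeeper,TBP,1
FBS/X2,bestkeeper,EF1A,2
FBS/X2,bestkeeper,GAPDH,3
FBS/X2,bestkeeper,RPLP0,4
FBS/X2,bestkeeper,ACTB,5
FBS/X2,normfinder,TBP,1
FBS/X2,normfinder,GAPDH,2
FBS/X2,normfinder,RPLP0,3
FBS/X2,normfinder,EF1A,4
FBS/X2,normfinder,ACTB,5
FBS/X2,genorm,EF1A,1
FBS/X2,genorm,TBP,1
FBS/X2,genorm,RPLP0,2
FBS/X2,genorm,GAPDH,3
FBS/X2,genorm,ACTB,4
ALL,delta_ct,GAPDH,1
ALL,delta_ct,TBP,2
ALL,delta_ct,EF1A,3
ALL,delta_ct,RPLP0,4
ALL,delta_ct,ACTB,5
ALL,bestkeeper,TBP,1
ALL,bestkeeper,GAPDH,2
ALL,bestkeeper,EF1A,3
ALL,bestkeeper,RPLP0,4
ALL,bestkeeper,ACTB,5
ALL,normfinder,GAPDH,1
ALL,normfinder,TBP,2
ALL,normfinder,EF1A,3
ALL,normfinder,RPLP0,4
ALL,normfinder,ACTB,5
ALL,genorm,EF1A,1
ALL,genorm,TBP,1
ALL,genorm,GAPDH,2
ALL,genorm,RPLP0,3
ALL,genorm,ACTB,4
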