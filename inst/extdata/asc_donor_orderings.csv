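stratum,algorithm,gene,position
ASC1,delta_ct,TBP,1
ASC1,delta_ct,RPLP0,2
ASC1,delta_ct,EF1A,3
ASC1,delta_ct,GAPDH,4
ASC1,delta_ct,ACTB,5
ASC1,bestkeeper,RPLP0,1
ASC1,bestkeeper,ACTB,2
ASC1,bestkeeper,TBP,3
ASC1,bestkeeper,EF1A,4
ASC1,bestkeeper,GAPDH,5
ASC1,normfinder,TBP,1
ASC1,normfinder,RPLP0,2
ASC1,normfinder,EF1A,3
ASC1,normfinder,GAPDH,4
ASC1,normfinder,ACTB,5
ASC1,genorm,EF1A,1
ASC1,genorm,GAPDH,1
ASC1,genorm,TBP,2
ASC1,genorm,RPLP0,3
ASC1,genorm,ACTB,4
ASC2,delta_ct,GAPDH,1
ASC2,delta_ct,EF1A,2
ASC2,delta_ct,RPLP0,3
ASC2,delta_ct,TBP,4
ASC2,delta_ct,ACTB,5
ASC2,bestkeeper,TBP,1
ASC2,bestkeeper,RPLP0,2
ASC2,bestkeeper,GAPDH,3
ASC2,bestkeeper,EF1A,4
ASC2,bestkeeper,ACTB,5
ASC2,normfinder,GAPDH,1
ASC2,normfinder,EF1A,2
ASC2,normfinder,RPLP0,3
ASC2,normfinder,TBP,4
ASC2,normfinder,ACTB,5
ASC2,genorm,RPLP0,1
ASC2,genorm,TBP,1
ASC2,genorm,GAPDH,2
ASC2,genorm,EF1A,3
ASC2,genorm,ACTB,4
ASC3,delta_ct,GAPDH,1
ASC3,delta_ct,TBP,2
ASC3,delta_ct,EF1A,3
ASC3,delta_ct,RPLP0,4
ASC3,delta_ct,ACTB,5
ASC3,bestkeeper,TBP,1
ASC3,bestkeeper,GAPDH,2
ASC3,bestkeeper,EF1A,3
ASC3,bestkeeper,RPLP0,4
ASC3,bestkeeper,ACTB,5
ASC3,normfinder,TBP,1
ASC3,normfinder,GAPDH,2
ASC3,normfinder,EF1A,3
ASC3,normfinder,RPLP0,4
ASC3,normfinder,ACTB,5
ASC3,genorm,TBP,1
ASC3,genorm,GAPDH,1
ASC3,genorm,EF1A,2
ASC3,genorm,RPLP0,3
ASC3,genorm,ACTB,4
ASC4,delta_ct,ACTB,1
ASC4,delta_ct,EF1A,2
ASC4,delta_ct,GAPDH,3
ASC4,delta_ct,RPLP0,4
ASC4,delta_ct,TBP,5
ASC4,bestkeeper,GAPDH,1
ASC4,bestkeeper,RPLP0,2
ASC4,bestkeeper,ACTB,3
ASC4,bestkeeper,EF1A,4
ASC4,bestkeeper,TBP,5
ASC4,normfinder,ACTB,1
ASC4,normfinder,EF1A,2
ASC4,normfinder,GAPDH,3
ASC4,normfinder,RPLP0,4
ASC4,normfinder,TBP,5
ASC4,genorm,ACTB,1
ASC4,genorm,GAPDH,1
ASC4,genorm,EF1A,2
ASC4,genorm,RPLP0,3
ASC4,genorm,TBP,4
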