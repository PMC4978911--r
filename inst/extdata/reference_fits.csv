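fit,quantity,value,tol
fig1a,slope,-0.73,0.05
fig1a,intercept,2.23,0.15
fig1a,r2,0.89,0.04
fig1b,slope,-0.87,0.05
fig1b,intercept,3.49,0.25
fig1b,r2,0.87,0.04
fig3,slope,0.91,0.05
fig3,intercept,-1.56,0.25
fig3,r2,0.90,0.04
unicellular,r2,0.66,0.06
pic,slope,-0.60,0.10
pic,r2,0.83,0.08
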