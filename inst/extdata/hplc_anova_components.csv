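# Published ANOVA components (sums of squares and degrees of freedom) of the
# chromatographic-quality regression model
component,ss,df
regression,253.357,6
residual,41.066,26
total,294.423,32
lack_of_fit,36.421,18
pure_error,5.006,8
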