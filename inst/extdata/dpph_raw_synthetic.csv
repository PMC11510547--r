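# SYNTHETIC replicate-level DPPH records consistent with the published mean
# inhibition points (t1 back-computed from t0 = 0.532; +/- half the printed
# replicate spread). For testing the long-format reader only.
concentration_mg_per_ml,t0,t1
1.50,0.532,0.4071
1.50,0.532,0.3909
1.88,0.532,0.3857
1.88,0.532,0.3804
3.00,0.532,0.3381
3.00,0.532,0.3365
3.75,0.532,0.2740
3.75,0.532,0.2580
7.50,0.532,0.0513
7.50,0.532,0.0497
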