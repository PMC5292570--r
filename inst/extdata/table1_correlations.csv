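# Published reference table: Pearson correlation coefficients between the RMS
# envelopes recorded simultaneously by wet Ag/AgCl and dry PPy electrodes from
# the same muscle fibers; 4 able-bodied subjects x 3 trials (n = 12).
subject,trial,r
1,1,0.82
1,2,0.83
1,3,0.87
2,1,0.76
2,2,0.87
2,3,0.83
3,1,0.83
3,2,0.85
3,3,0.88
4,1,0.97
4,2,0.96
4,3,0.96
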