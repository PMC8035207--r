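band,stock_initial,stock_initial_lo,stock_initial_hi,stock_final,stock_final_lo,stock_final_hi,cover_initial,cover_final
500-1200,71.89,62.97,81.37,88.85,70.79,105.86,237820.21,230115.49
1200-2000,73.85,65.11,81.83,73.25,65.47,80.93,175122.11,171684.02
2000-2800,63.33,49.72,76.63,62.96,52.16,74.09,94961.05,93844.90
2800-3600,56.69,50.52,63.12,59.60,49.13,74.09,39172.57,38744.63
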