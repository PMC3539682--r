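metric,variant,C,N,M,K,G
cv_mm_per_s,control,751.9,657.9,680.2,714.3,NA
cv_mm_per_s,caf,602.4,588.2,595.2,578.0,909.1
erp_ms,control,302,234,207,192,NA
erp_ms,caf,152,137,133,123,116
wl_mm,control,227.1,153.9,140.8,137.1,NA
wl_mm,caf,91.6,80.6,79.2,71.1,105.4
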