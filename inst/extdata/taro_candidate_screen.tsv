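gene_id	mean_fpkm	sd_fpkm	cv_percent
ACY-1	34.95	6.22	17.80
USP25	12.05	2.17	17.98
CCX4L	18.09	3.46	19.13
LYK3	15.34	2.96	19.28
PIA2	65.07	12.85	19.75
Armc8	12.15	2.40	19.78
COX10	22.46	4.52	20.14
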