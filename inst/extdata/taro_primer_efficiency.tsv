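gene_id	efficiency_percent
ACY-1	99.1
USP25	105.2
CCX4L	96.5
LYK3	102.2
PIA2	95.8
Armc8	104.2
COX10	96.8
Actin	98.1
beta-tubulin	99.5
EF-1alpha	94.5
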