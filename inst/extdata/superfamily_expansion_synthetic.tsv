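superfamily_id	expansion_r
a.176.4	0.95
a.33.4	0.88
a.44.9	0.8
a.22.2	0.74
a.117.8	0.55
a.106.6	0.41
a.190.4	0.33
a.128.4	0.2
a.102.1	0.15
a.160.7	0.07
a.13.2	0.02
a.20.7	-0.1
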