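domain_id	superfamily_id
d1a01	a.106.6
d1b02	a.117.8
d1c03	a.128.4
d1d04	a.190.4
d1e05	a.160.7
d1f06	a.106.6
d1g07	a.117.8
d1h08	a.20.7
d1i09	a.160.7
d1j10	a.176.4
d1k11	a.20.7
d1l12	a.106.6
d1m13	a.106.6
d1n14	a.190.4
d1o15	a.22.2
d1p16	a.117.8
d1q17	a.190.4
d1r18	a.176.4
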