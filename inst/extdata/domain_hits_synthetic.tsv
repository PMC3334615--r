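d1a01	PRT029	52.9	120	8	1	1	120	5	124	1e-20	180
d1b02	PRT012	21.3	120	8	1	1	120	5	124	1e-20	180
d1c03	PRT009	24.3	120	8	1	1	120	5	124	1e-20	180
d1d04	PRT035	80.7	120	8	1	1	120	5	124	1e-20	180
d1e05	PRT040	75	120	8	1	1	120	5	124	1e-20	180
d1f06	PRT038	26.8	120	8	1	1	120	5	124	1e-20	180
d1g07	PRT040	67.2	120	8	1	1	120	5	124	1e-20	180
d1h08	PRT039	71.6	120	8	1	1	120	5	124	1e-20	180
d1i09	PRT035	45.9	120	8	1	1	120	5	124	1e-20	180
d1j10	PRT011	64.3	120	8	1	1	120	5	124	1e-20	180
d1k11	PRT038	30.5	120	8	1	1	120	5	124	1e-20	180
d1l12	PRT004	31.8	120	8	1	1	120	5	124	1e-20	180
d1m13	PRT015	55.2	120	8	1	1	120	5	124	1e-20	180
d1n14	PRT029	88.2	120	8	1	1	120	5	124	1e-20	180
d1o15	PRT031	42.5	120	8	1	1	120	5	124	1e-20	180
d1p16	PRT011	94.8	120	8	1	1	120	5	124	1e-20	180
d1q17	PRT003	68.9	120	8	1	1	120	5	124	1e-20	180
d1r18	PRT027	45.3	120	8	1	1	120	5	124	1e-20	180
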