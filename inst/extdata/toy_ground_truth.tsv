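Signature	ToyType1::S001	ToyType1::S002	ToyType1::S003	ToyType1::S004
TS01	6176	6650	4279	13299
TS02	9815	1967	696	0
TS03	1498	5023	287	416
TS04	3956	0	0	0
TS05	1294	0	0	0
TS06	1163	0	0	0
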