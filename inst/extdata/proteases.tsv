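name	contexts	specificity	min_length	max_length	max_missed
Trypsin	K|,R|	full	5	60	3
Semi-Trypsin	K|,R|	semi	5	60	3
Non-Specific		nonspecific	5	60	0
OgpA	|T,|S	full	5	60	3
IMPa	|T,|S	full	5	60	3
StcE	[ST]x|[ST]	full	5	60	3
OgpA-Trypsin	|T,|S,K|,R|	full	5	60	12
IMPa-Trypsin	|T,|S,K|,R|	full	5	60	12
StcE-Trypsin	[ST]x|[ST],K|,R|	full	5	60	12
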