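N1
N1H1
N2
N2H1
N2H2
N1A1
N1H1A1
N1H1A2
N2H1A1
N2H2A1
N2H2A2
N2H1A2
N1G1
N1H1G1
N1H1G2
N2H1G1
N2H2G1
N2H2G2
N2H1G2
N1H1A1G1
N2H1A1G1
N2H2A1G1
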