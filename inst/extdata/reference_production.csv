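year,B,E,P,ep_percent
2002,1.74,9.14,23.70,38.57
2003,2.22,5.99,30.28,19.78
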