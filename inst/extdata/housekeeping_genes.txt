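ACTB
GAPDH
TUBB
TBP
POLR2A
RPLP0
SDHA
UBC
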