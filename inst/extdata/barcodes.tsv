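AAAC-1
AAAG-1
AACT-1
AAGG-1
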