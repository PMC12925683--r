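population	carriers	noncarriers
non_finnish_european	56	589929
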