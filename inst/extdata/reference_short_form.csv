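item_id
SCI-2
SCI-8
SCI-26
SCI-47
SCI-4
SCI-30
SCI-5
SCI-37
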