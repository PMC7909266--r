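# Filler tokens treated as empty speech. One entry per line; multi-word
# entries match as contiguous token sequences after normalization.
um
uh
er
hm
mhm
you know
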