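# Phrase patterns counted as empty speech in addition to fillers and
# unrecognizable words. Matched as contiguous normalized token sequences.
or something
i guess
sort of
kind of
et cetera
blah blah
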