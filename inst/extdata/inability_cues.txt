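# Cue phrases for statements about inability to decipher the picture or
# retrieve a word. Matched as contiguous normalized token sequences.
can't think of
can't think
i'm not sure
i'm not quite sure
not quite sure
i don't know
i can't remember
can't remember
i forget
what do you call
whatever that is
i don't recall
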