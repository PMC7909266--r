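Provenance notes for the packaged picnic-scene content-unit lexicon
(picnic_cu_lexicon.tsv / picnic_cu_lexicon.json)

The lexicon reproduces the published 64-concept inventory for the WAB-R
"Picnic Scene" picture-description task (64 parent content units; referent
sub-units for the 12 ambiguous CUs that speech output can disambiguate).
Three editorial corrections were applied when transcribing the published
table into the fixture:

1. CU #30 is printed as "Nasket"; this is an evident typographical error for
   "basket" (an unambiguous entity in the scene). The fixture stores
   "basket".

2. CU #31 is printed as "(Man's) glasses". Stripping the parenthetical would
   leave the head "glasses", which already belongs to CU #24 ("Glass, cup,
   glasses") and would make variant lookup ambiguous. The fixture therefore
   stores the full two-token phrase "man's glasses".

3. CU #57 lists "(playing) music" alongside the plain variant "music".
   After parenthetical stripping both reduce to the same head, so the
   fixture keeps a single "music" variant (same CU; no information lost).

Variants printed with parentheses, e.g. "caught (a fish)", are stored
verbatim; the loader strips the parenthetical into an optional-context note
and matches on the head phrase.
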