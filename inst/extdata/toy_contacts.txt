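s01 s02
s01 s03
s02 s03
s03 s04
s04 s05
s05 s06
s06 s07
s02 s07
s01 s02 s03
s03 s04 s05
s05 s06 s07
s01 s02 s03 s04
s04 s05 s06 s07
s01 s03 s05 s07 s08
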