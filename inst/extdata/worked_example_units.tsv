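pair	item	component	units
logo_grapheme	word_enthusiasm	logo	hand_radical|wan|fire_dots|heart_radical|qing_top|moon
logo_grapheme	word_eye	logo	mu|gen|mu|qing_top|moon
phonology	pinyin_reqing	phonology	r|e|tone4|q|ing|tone2
phonology	pinyin_yanjing	phonology	y|an|tone3|j|ing|tone1
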