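# Default initial-state annotator patterns: priority <TAB> regex <TAB> tag.
# Patterns match against the raw note text; matched spans are projected onto
# tokens (that is why the USERNAME pattern may contain a space).
# Note: the DATE pattern repeats the \d{4} alternative; the duplication is
# preserved as published and is harmless (alternation is first-match).
1	[A-Za-z]{2,3} [0-9]{2,3}	B(USERNAME)
2	Hospital|HOSPITAL	I(HOSPITAL)
3	\w+@\w+\.[A-Za-z]{3}	B(EMAIL)
4	St|Street|Avenue|Lane|Drive|Rd|Road|Circle|Place	I(STREET)
5	\d{4}|\d{2}-\d{2}-\d{2}|\d{4}	B(DATE)
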