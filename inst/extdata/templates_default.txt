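# Default transformation-rule templates: one template per line, conditions
# comma-separated as feature@offset; "tag" refers to the current tag
# sequence, everything else to columns of the feature table.
token@0
token@0,tag@-1
length@-1,token@0
all_digits@0,pos@0
prefix4@0
suffix4@0
section@0,all_digits@0
token@-1
token@1
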