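alias	gene	spec	note
EGFRvIII	EGFR	del:6-273	curator-supplied coordinates (exon 2-7 deletion product); not taken from the variant table
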