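atom	do_id	name	ncit_xref
glioblastoma	3075	adult glioblastoma multiforme
lung cancer	1324	lung cancer
endometrial cancer	1380	endometrial cancer
myeloid leukemia	8692	myeloid leukemia
rhabdomyosarcoma	3247	rhabdomyosarcoma
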