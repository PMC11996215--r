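1	555	"S1"
555	1035	"systolic"
1035	1515	"S2"
1515	2235	"diastolic"
2235	2795	"S1"
2795	3275	"systolic"
3275	3755	"S2"
3755	4555	"diastolic"
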