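domain	total_reads	high_quality_reads
bacteria	959619	958122
fungi	935153	931844
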