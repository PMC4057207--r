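run	raw_reads	mapped_reads	genomic_positions
mMtr4-1	15135078	10853534	651551
mControl-1	16348780	11708310	652128
mMtr4-2	40464271	34308545	1124968
mControl-2	9124467	7195942	582256
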