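chrm	strand	mode_coordinate	kd_reads	ctrl_reads	annotation
chr9	+	122592015	65	1	mir138 5' leader
chrX	-	50407504	250	4	mir322 5' leader
chr9	+	40613015	332	43	last intron of Hspa8
chr15	+	85537754	40	6	let7b 5' leader
chrX	-	50406290	136	24	mir322 3' UTR terminus
chr6	-	48474268	37	10	unannotated antisense locus
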