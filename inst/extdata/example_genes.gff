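##gff-version  3
E01	Prodigal_v2.6.3	CDS	101	600	120.5	+	0	ID=g001;partial=00;start_type=ATG;rbs_motif=None;rbs_spacer=None;gc_cont=0.45
E01	Prodigal_v2.6.3	CDS	701	1200	98.2	-	0	ID=g002;partial=00;start_type=ATG;rbs_motif=None;rbs_spacer=None;gc_cont=0.44
E02	Prodigal_v2.6.3	CDS	1	450	55.1	+	0	ID=g003;partial=10;start_type=Edge;rbs_motif=None;rbs_spacer=None;gc_cont=0.47
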