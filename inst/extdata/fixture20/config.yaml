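proteins: proteins.fasta
similarity: similarity.tsv
clusters: clusters.tsv
alignments: alignments
go: go_annotations.tsv
pfam: pfam_domains.tsv
clan_map: clan_map.tsv
bins: 4
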