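chrom	n_snps
Chr1	94
Chr2	75
Chr3	62
Chr4	73
Chr5	67
Chr6	63
Chr7	70
Chr8	59
Chr9	69
Chr10	60
Chr11	47
Chr12	44
Chr13	64
Chr14	68
Chr15	58
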