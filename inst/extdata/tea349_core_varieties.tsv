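population	size	core_count
1	159	32
2	72	14
3	51	10
4	50	10
5	17	4
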