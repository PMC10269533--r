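fasta: tcpp_synthetic.fasta
protein: TcpP_synthetic
tm_start: 161
tm_end: 181
target: 172.0
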