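>INS_A human insulin A chain (mature)
GIVEQCCTSICSLYQLENYCN
>INS_B human insulin B chain (mature)
FVNQHLCGSHLVEALYLVCGERGFFYTPKT
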