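>INS_A human insulin A chain (mature)
GIVEQCCTSICSLYQLENYCN
>INS_B human insulin B chain (mature)
FVNQHLCGSHLVEALYLVCGERGFFYTPKT
>BSA_MATURE bovine serum albumin, mature chain
DTHKSEIAHRFKDLGEEHFKGLVLIAFSQYLQQCPFDEHVKLVNELTEFAKTCVADESHA
GCEKSLHTLFGDELCKVASLRETYGDMADCCEKQEPERNECFLSHKDDSPDLPKLKPDPN
TLCDEFKADEKKFWGKYLYEIARRHPYFYAPELLYYANKYNGVFQECCQAEDKGACLLPK
IETMREKVLASSARQRLRCASIQKFGERALKAWSVARLSQKFPKAEFVEVTKLVTDLTKV
HKECCHGDLLECADDRADLAKYICDNQDTISSKLKECCDKPLLEKSHCIAEVEKDAIPEN
LPPLTADFAEDKDVCKNYQEAKDAFLGSFLYEYSRRHPEYAVSVLLRLAKEYEATLEECC
AKDDPHACYSTVFDKLKHLVDEPQNLIKQNCDQFEKLGEYGFQNALIVRYTRKVPQVSTP
TLVEVSRSLGKVGTRCCTKPESERMPCTEDYLSLILNRLCVLHEKTPVSEKVTKCCTESL
VNRRPCFSALTPDETYVPKAFDEKLFTFHADICTLPDTEKQIKKQTALVELLKHKPKATE
EQLKTVMENFVAFVDKCCAADDKEACFAVEGPKLVVSTQTALA
>SYN1 synthetic protein 1 (random composition, fixed seed)
LEKVAKIYLGFGSAVGTAGTLKTSRETYISRLLLIHRPFKFHDASVEFPHELASVVFPHS
RHTFAKEHKSEGRFLCNCTTSALMVLVNAKHIQGSASAAKIVINRYSSLENGRTMRPREC
QWRVAHVRALHTGGLTQKNKGDQDGRPRMLVDGESTKTADQISKRELNRSGIGPQNIIKV
ILKVESDRERPGLNDPSLDNAIYSCNRCHPGDLLVASDKNGMNCVICTAKSFAWGWERVT
VNDEPRLTSTWAPLPEIQGK
>SYN2 synthetic protein 2 (random composition, fixed seed)
KRTENLHKTRGHERLVDVLNEAVYFDSLNKHRAVIDPDEGVLGVFSSPKQLRGSVVWGHW
ATPESLAYRSCVTGSTTLLASSELLYMDSNHTKIEEGQHAHTEPGTSQRENSDQPSDEDP
HSYTPTYTVAKCYSYQSDRMNVIGDAHITSRTWFVETKSSVDMAHYIKGVSEPAEELKLQ
DGTDLIQNLFVPLNSEGLLLIALKGPICSTSFNPKSIRHGTWKILEECQFEQPLEGGRVS
VFTSASELEPVGYRADTKLIQKDKNRSHQKRDHPVPKYHQAVDASGKPIVSTELALLFLA
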