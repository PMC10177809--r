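>g01_polyA
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
>g02_u_flanks
UUUUUUUUUUUUUUUUUUUUAUUUUUUUUUUUUUUUUUUUU
>g03_c_flanks
CCCCCCCCCCCCCCCCCCCCACCCCCCCCCCCCCCCCCCCC
>g04_g_flanks
GGGGGGGGGGGGGGGGGGGGAGGGGGGGGGGGGGGGGGGGG
>g05_acgu_repeat
ACGUACGUACGUACGUACGUACGUACGUACGUACGUACGUA
>g06_au_repeat
AUAUAUAUAUAUAUAUAUAUAUAUAUAUAUAUAUAUAUAUA
>g07_ag_repeat
AGAGAGAGAGAGAGAGAGAGAGAGAGAGAGAGAGAGAGAGA
>g08_motif_polyA
AAAAAAAAAAAAAAAAAAAAAGGACUCAAAAAAAAAAAAAA
>g09_motif_gc
CCCCCCCCCCGGGGGGGGGGAGGACUCCCCCCCCGGGGGGG
>g10_mixed
CCCUCGGAUUCCAGACGGCAAAUAAACGACUGGAACCUUUC
>g11_mixed
GGGGGAAGAGUACUUCCCUGAGACCGGUUUAAGUCUUUGCC
>g12_motif_mixed
UAAUUUAGCCAAGGACAAUCAGGACUCACUUUCUGAUGGAC
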