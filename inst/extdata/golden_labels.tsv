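g01_polyA	0
g02_u_flanks	0
g03_c_flanks	0
g04_g_flanks	0
g05_acgu_repeat	0
g06_au_repeat	0
g07_ag_repeat	0
g08_motif_polyA	1
g09_motif_gc	1
g10_mixed	0
g11_mixed	0
g12_motif_mixed	1
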