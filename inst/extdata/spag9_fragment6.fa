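>SPAG9_fragment6 60-residue segment of cancer-testis antigen SPAG9
KHIEVQVAQETRNVSTGSAENEEKSEVQAIIESTPELDMDKDLSGYKGSS
TPTKGIENKA
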