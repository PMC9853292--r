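pattern	guild
Methanopyrales	methanogen
Methanococcales	methanogen
Methanobacteriales	methanogen
Methanomicrobiales	methanogen
Methanosarcinales	methanogen
Methanocellales	methanogen
Methanomassiliicoccales	methanogen
Methylococcales	methanotroph
Methylomirabilales	methanotroph
Methylacidiphilales	methanotroph
Methylocystis	methanotroph
Methylosinus	methanotroph
Methylocella	methanotroph
Methylocapsa	methanotroph
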