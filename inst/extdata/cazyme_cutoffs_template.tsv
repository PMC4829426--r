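family	cutoff
GH16	1e-05
GH17	1e-05
GH30	1e-05
GH92	1e-05
GH13	1e-05
GH3	1e-05
CBM50	1e-05
PL7	1e-05
CE4	1e-05
GH29	1e-05
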