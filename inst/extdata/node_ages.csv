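clade,age
angiospermae,137
mesangiospermae,135
magnoliids,121
eudicots,124
rosids,110
fabids,101
nfixing,94
sapindales,84
asterids,114
coreasterids,108
ericales,106
coreericales,98
styracoids,90
theoids,89
ericoids,80
euasterids,102
campanulids,92
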