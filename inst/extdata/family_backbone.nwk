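(Schisandraceae,((Magnoliaceae,Lauraceae)magnoliids,((((Rosaceae,Fagaceae)nfixing,Euphorbiaceae)fabids,(Rutaceae,Sapindaceae)sapindales)rosids,(Cornaceae,((Pentaphylacaceae,((Symplocaceae,Styracaceae)styracoids,(Theaceae,(Clethraceae,Ericaceae)ericoids)theoids)coreericales)ericales,(Oleaceae,(Aquifoliaceae,Araliaceae)campanulids)euasterids)coreasterids)asterids)eudicots)mesangiospermae)angiospermae;
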