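e.g.
i.e.
i.v.
i.m.
p.o.
dr.
vs.
etc.
fig.
approx.
et al.
spp.
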