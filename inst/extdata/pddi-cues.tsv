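cue	note
AUC	area-under-curve mention
Cmax	peak concentration
clearance	pharmacokinetic parameter
concentration	covers concentration(s)
exposure	systemic exposure
half-life	elimination half-life
pharmacokinetic	covers pharmacokinetic(s)
bioavailab	covers bioavailability
absorption	absorption change
inhibit	covers inhibits/inhibited/inhibitor
induc	covers induces/induced/induction
increas	covers increase(d/s)
decreas	covers decrease(d/s)
elevat	covers elevate(d)/elevation
reduc	covers reduce(d)/reduction
interact	covers interaction(s)/interacts
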