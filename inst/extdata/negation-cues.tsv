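cue	note
no effect	explicit denial
did not	negated verb frame
does not	negated verb frame
no significant	magnitude denial
not altered	negated outcome
was not	negated auxiliary
were not	negated auxiliary
no clinically	clinical-relevance denial
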