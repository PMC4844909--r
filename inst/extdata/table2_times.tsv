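participant	group	scenario	category
Expert	expert	1	<1h
Expert	expert	2	<1h
Expert	expert	3	<1h
Nonexpert 1	nonexpert	1	<1h
Nonexpert 1	nonexpert	2	<1h
Nonexpert 1	nonexpert	3	<1h
Nonexpert 2	nonexpert	1	1-3h
Nonexpert 2	nonexpert	2	<1h
Nonexpert 2	nonexpert	3	<1h
Nonexpert 3	nonexpert	1	3-5h
Nonexpert 3	nonexpert	2	3-5h
Nonexpert 3	nonexpert	3	>5h
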