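participant	group	scenario	rating
Expert	expert	1	2
Expert	expert	2	4
Expert	expert	3	2
Nonexpert 1	nonexpert	1	4
Nonexpert 1	nonexpert	2	5
Nonexpert 1	nonexpert	3	2
Nonexpert 2	nonexpert	1	4
Nonexpert 2	nonexpert	2	5
Nonexpert 2	nonexpert	3	2
Nonexpert 3	nonexpert	1	3
Nonexpert 3	nonexpert	2	3
Nonexpert 3	nonexpert	3	2
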