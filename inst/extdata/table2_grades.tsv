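# NCI CTCAE grade distributions of chemotherapy-induced neutropenia (N = 1676)
# and taxane-related sensory neuropathy (N = 1279). Cases are neutropenia
# grade >=3 and neuropathy grade >=2.
grade	neutropenia_n	neuropathy_n
0	733	271
1	199	648
2	245	304
3	293	56
4	206	0
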