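sample_id	gene	variant_id	allele1	allele2
A3H001	A3H	rs140936762	AAC	AAC
A3H001	A3H	rs139293	G	G
A3H001	A3H	rs139297	C	C
A3H001	A3H	rs139298	G	G
A3H001	A3H	rs139300	G	G
A3H001	A3H	rs139302	C	C
A3H001	A3H	rs139294	G	G
A3H002	A3H	rs140936762	AAC	AAC
A3H002	A3H	rs139293	G	G
A3H002	A3H	rs139297	C	C
A3H002	A3H	rs139298	G	G
A3H002	A3H	rs139300	G	G
A3H002	A3H	rs139302	C	C
A3H002	A3H	rs139294	G	G
A3H003	A3H	rs140936762	AAC	AAC
A3H003	A3H	rs139293	G	G
A3H003	A3H	rs139297	C	C
A3H003	A3H	rs139298	G	G
A3H003	A3H	rs139300	G	G
A3H003	A3H	rs139302	C	C
A3H003	A3H	rs139294	G	G
A3H004	A3H	rs140936762	AAC	AAC
A3H004	A3H	rs139293	G	G
A3H004	A3H	rs139297	C	C
A3H004	A3H	rs139298	G	G
A3H004	A3H	rs139300	G	G
A3H004	A3H	rs139302	C	C
A3H004	A3H	rs139294	G	G
A3H005	A3H	rs140936762	AAC	AAC
A3H005	A3H	rs139293	G	G
A3H005	A3H	rs139297	C	C
A3H005	A3H	rs139298	G	G
A3H005	A3H	rs139300	G	G
A3H005	A3H	rs139302	C	C
A3H005	A3H	rs139294	G	G
A3H006	A3H	rs140936762	AAC	AAC
A3H006	A3H	rs139293	G	G
A3H006	A3H	rs139297	C	C
A3H006	A3H	rs139298	G	G
A3H006	A3H	rs139300	G	G
A3H006	A3H	rs139302	C	C
A3H006	A3H	rs139294	G	G
A3H007	A3H	rs140936762	AAC	AAC
A3H007	A3H	rs139293	G	G
A3H007	A3H	rs139297	C	C
A3H007	A3H	rs139298	G	G
A3H007	A3H	rs139300	G	G
A3H007	A3H	rs139302	C	C
A3H007	A3H	rs139294	C	G
A3H008	A3H	rs140936762	AAC	AAC
A3H008	A3H	rs139293	G	G
A3H008	A3H	rs139297	C	C
A3H008	A3H	rs139298	G	G
A3H008	A3H	rs139300	G	G
A3H008	A3H	rs139302	C	C
A3H008	A3H	rs139294	C	G
A3H009	A3H	rs140936762	AAC	AAC
A3H009	A3H	rs139293	G	G
A3H009	A3H	rs139297	C	C
A3H009	A3H	rs139298	G	G
A3H009	A3H	rs139300	G	G
A3H009	A3H	rs139302	C	C
A3H009	A3H	rs139294	C	G
A3H010	A3H	rs140936762	AAC	AAC
A3H010	A3H	rs139293	G	G
A3H010	A3H	rs139297	C	C
A3H010	A3H	rs139298	G	G
A3H010	A3H	rs139300	G	G
A3H010	A3H	rs139302	C	C
A3H010	A3H	rs139294	C	G
A3H011	A3H	rs140936762	AAC	AAC
A3H011	A3H	rs139293	G	G
A3H011	A3H	rs139297	C	C
A3H011	A3H	rs139298	G	G
A3H011	A3H	rs139300	G	G
A3H011	A3H	rs139302	C	C
A3H011	A3H	rs139294	C	G
A3H012	A3H	rs140936762	AAC	AAC
A3H012	A3H	rs139293	G	G
A3H012	A3H	rs139297	C	C
A3H012	A3H	rs139298	G	G
A3H012	A3H	rs139300	G	G
A3H012	A3H	rs139302	C	C
A3H012	A3H	rs139294	C	G
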