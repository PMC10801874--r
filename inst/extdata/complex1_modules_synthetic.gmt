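N_MODULE_EXAMPLE	synthetic example grouping, not curated truth	NDUFV1	NDUFV2	NDUFS1	NDUFA2	NDUFA12
Q_MODULE_EXAMPLE	synthetic example grouping, not curated truth	NDUFS2	NDUFS3	NDUFS7	NDUFS8	NDUFA5
PP_MODULE_EXAMPLE	synthetic example grouping, not curated truth	NDUFA8	NDUFA1	NDUFA13	NDUFB7	NDUFS5
PD_MODULE_EXAMPLE	synthetic example grouping, not curated truth	NDUFB4	NDUFB8	NDUFB10	NDUFB11	NDUFAB1
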