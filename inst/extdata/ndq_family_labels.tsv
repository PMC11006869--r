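id	class	subgroup_letter
Subgroup1_001	Subgroup1	L
Subgroup1_002	Subgroup1	I
Subgroup1_003	Subgroup1	L
Subgroup1_004	Subgroup1	I
Subgroup1_005	Subgroup1	L
Subgroup1_006	Subgroup1	I
Subgroup1_007	Subgroup1	L
Subgroup1_008	Subgroup1	I
Subgroup1_009	Subgroup1	L
Subgroup1_010	Subgroup1	I
Subgroup1_011	Subgroup1	L
Subgroup1_012	Subgroup1	I
Subgroup1_013	Subgroup1	L
Subgroup1_014	Subgroup1	I
Subgroup1_015	Subgroup1	L
Subgroup1_016	Subgroup1	I
Subgroup1_017	Subgroup1	L
Subgroup1_018	Subgroup1	I
Subgroup1_019	Subgroup1	L
Subgroup1_020	Subgroup1	I
Subgroup1_021	Subgroup1	L
Subgroup1_022	Subgroup1	I
Subgroup1_023	Subgroup1	L
Subgroup1_024	Subgroup1	I
Subgroup1_025	Subgroup1	L
Subgroup1_026	Subgroup1	I
Subgroup1_027	Subgroup1	L
Subgroup1_028	Subgroup1	I
Subgroup1_029	Subgroup1	L
Subgroup1_030	Subgroup1	I
Subgroup2_001	Subgroup2	E
Subgroup2_002	Subgroup2	E
Subgroup2_003	Subgroup2	E
Subgroup2_004	Subgroup2	E
Subgroup2_005	Subgroup2	E
Subgroup2_006	Subgroup2	E
Subgroup2_007	Subgroup2	E
Subgroup2_008	Subgroup2	E
Subgroup2_009	Subgroup2	E
Subgroup2_010	Subgroup2	E
Subgroup2_011	Subgroup2	E
Subgroup2_012	Subgroup2	E
Subgroup2_013	Subgroup2	E
Subgroup2_014	Subgroup2	E
Subgroup2_015	Subgroup2	E
Subgroup2_016	Subgroup2	E
Subgroup2_017	Subgroup2	E
Subgroup2_018	Subgroup2	E
Subgroup2_019	Subgroup2	E
Subgroup2_020	Subgroup2	E
Subgroup2_021	Subgroup2	E
Subgroup2_022	Subgroup2	E
Subgroup2_023	Subgroup2	E
Subgroup2_024	Subgroup2	E
Subgroup2_025	Subgroup2	E
Subgroup2_026	Subgroup2	E
Subgroup2_027	Subgroup2	E
Subgroup2_028	Subgroup2	E
Subgroup2_029	Subgroup2	E
Subgroup2_030	Subgroup2	E
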