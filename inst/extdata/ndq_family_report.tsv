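id	motif	motif_ok	length_ok	unique_ok	kept	subgroup_residue	subgroup	representative
REF	RNDQDK	TRUE	TRUE	TRUE	TRUE	L	Subgroup1	REF
Subgroup1_001	RNDQDK	TRUE	TRUE	TRUE	TRUE	L	Subgroup1	Subgroup1_001
Subgroup1_002	RNDQDK	TRUE	TRUE	TRUE	TRUE	I	Subgroup1	Subgroup1_002
Subgroup1_003	RNDQDK	TRUE	TRUE	TRUE	TRUE	L	Subgroup1	Subgroup1_003
Subgroup1_004	RNDQDK	TRUE	TRUE	TRUE	TRUE	I	Subgroup1	Subgroup1_004
Subgroup1_005	RNDQDK	TRUE	TRUE	TRUE	TRUE	L	Subgroup1	Subgroup1_005
Subgroup1_006	RNDQDK	TRUE	TRUE	TRUE	TRUE	I	Subgroup1	Subgroup1_006
Subgroup1_007	RNDQDK	TRUE	TRUE	TRUE	TRUE	L	Subgroup1	Subgroup1_007
Subgroup1_008	RNDQDK	TRUE	TRUE	TRUE	TRUE	I	Subgroup1	Subgroup1_008
Subgroup1_009	RNDQDK	TRUE	TRUE	TRUE	TRUE	L	Subgroup1	Subgroup1_009
Subgroup1_010	RNDQDK	TRUE	TRUE	TRUE	TRUE	I	Subgroup1	Subgroup1_010
Subgroup1_011	RNDQDK	TRUE	TRUE	TRUE	TRUE	L	Subgroup1	Subgroup1_011
Subgroup1_012	RNDQDK	TRUE	TRUE	TRUE	TRUE	I	Subgroup1	Subgroup1_012
Subgroup1_013	RNDQDK	TRUE	TRUE	TRUE	TRUE	L	Subgroup1	Subgroup1_013
Subgroup1_014	RNDQDK	TRUE	TRUE	TRUE	TRUE	I	Subgroup1	Subgroup1_014
Subgroup1_015	RNDQDK	TRUE	TRUE	TRUE	TRUE	L	Subgroup1	Subgroup1_015
Subgroup1_016	RNDQDK	TRUE	TRUE	TRUE	TRUE	I	Subgroup1	Subgroup1_016
Subgroup1_017	RNDQDK	TRUE	TRUE	TRUE	TRUE	L	Subgroup1	Subgroup1_017
Subgroup1_018	RNDQDK	TRUE	TRUE	TRUE	TRUE	I	Subgroup1	Subgroup1_018
Subgroup1_019	RNDQDK	TRUE	TRUE	TRUE	TRUE	L	Subgroup1	Subgroup1_019
Subgroup1_020	RNDQDK	TRUE	TRUE	TRUE	TRUE	I	Subgroup1	Subgroup1_020
Subgroup1_021	RNDQDK	TRUE	TRUE	TRUE	TRUE	L	Subgroup1	Subgroup1_021
Subgroup1_022	RNDQDK	TRUE	TRUE	TRUE	TRUE	I	Subgroup1	Subgroup1_022
Subgroup1_023	RNDQDK	TRUE	TRUE	TRUE	TRUE	L	Subgroup1	Subgroup1_023
Subgroup1_024	RNDQDK	TRUE	TRUE	TRUE	TRUE	I	Subgroup1	Subgroup1_024
Subgroup1_025	RNDQDK	TRUE	TRUE	TRUE	TRUE	L	Subgroup1	Subgroup1_025
Subgroup1_026	RNDQDK	TRUE	TRUE	TRUE	TRUE	I	Subgroup1	Subgroup1_026
Subgroup1_027	RNDQDK	TRUE	TRUE	TRUE	TRUE	L	Subgroup1	Subgroup1_027
Subgroup1_028	RNDQDK	TRUE	TRUE	TRUE	TRUE	I	Subgroup1	Subgroup1_028
Subgroup1_029	RNDQDK	TRUE	TRUE	TRUE	TRUE	L	Subgroup1	Subgroup1_029
Subgroup1_030	RNDQDK	TRUE	TRUE	TRUE	TRUE	I	Subgroup1	Subgroup1_030
Subgroup2_001	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_001
Subgroup2_002	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_002
Subgroup2_003	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_003
Subgroup2_004	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_004
Subgroup2_005	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_005
Subgroup2_006	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_006
Subgroup2_007	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_007
Subgroup2_008	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_008
Subgroup2_009	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_009
Subgroup2_010	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_010
Subgroup2_011	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_011
Subgroup2_012	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_012
Subgroup2_013	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_013
Subgroup2_014	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_014
Subgroup2_015	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_015
Subgroup2_016	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_016
Subgroup2_017	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_017
Subgroup2_018	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_018
Subgroup2_019	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_019
Subgroup2_020	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_020
Subgroup2_021	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_021
Subgroup2_022	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_022
Subgroup2_023	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_023
Subgroup2_024	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_024
Subgroup2_025	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_025
Subgroup2_026	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_026
Subgroup2_027	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_027
Subgroup2_028	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_028
Subgroup2_029	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_029
Subgroup2_030	RNDQDK	TRUE	TRUE	TRUE	TRUE	E	Subgroup2	Subgroup2_030
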