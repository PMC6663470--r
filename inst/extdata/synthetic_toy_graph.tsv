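src	dst	weight
n002	n003	1
n001	n004	1
n003	n004	1
n003	n005	1
n001	n006	1
n003	n006	1
n005	n006	1
n001	n007	1
n003	n007	1
n004	n007	1
n005	n007	1
n006	n007	1
n001	n008	1
n002	n008	1
n003	n008	1
n005	n008	1
n007	n008	1
n001	n009	1
n004	n009	1
n006	n009	1
n001	n010	1
n005	n010	1
n009	n010	1
n001	n011	1
n003	n011	1
n005	n011	1
n003	n012	1
n005	n012	1
n006	n012	1
n010	n012	1
n011	n012	1
n013	n015	1
n014	n015	1
n011	n016	1
n013	n016	1
n014	n016	1
n006	n017	1
n009	n017	1
n013	n017	1
n014	n017	1
n016	n017	1
n010	n018	1
n014	n018	1
n015	n018	1
n016	n018	1
n007	n019	1
n013	n019	1
n014	n019	1
n017	n019	1
n010	n020	1
n014	n020	1
n015	n020	1
n017	n020	1
n018	n020	1
n013	n021	1
n017	n021	1
n003	n022	1
n004	n022	1
n011	n022	1
n013	n022	1
n015	n022	1
n018	n022	1
n019	n022	1
n020	n022	1
n007	n023	1
n017	n023	1
n018	n023	1
n019	n023	1
n021	n023	1
n022	n023	1
n013	n024	1
n020	n024	1
n021	n024	1
n004	n025	1
n012	n025	1
n023	n025	1
n025	n026	1
n021	n027	1
n025	n027	1
n002	n028	1
n003	n028	1
n007	n028	1
n025	n028	1
n027	n028	1
n016	n029	1
n017	n029	1
n022	n029	1
n026	n029	1
n028	n029	1
n001	n030	1
n016	n030	1
n026	n030	1
n028	n030	1
n008	n031	1
n015	n031	1
n029	n031	1
n008	n032	1
n013	n032	1
n030	n032	1
n031	n032	1
n010	n033	1
n029	n033	1
n032	n033	1
n006	n034	1
n022	n034	1
n026	n034	1
n027	n034	1
n028	n034	1
n029	n034	1
n031	n034	1
n032	n034	1
n004	n035	1
n009	n035	1
n013	n035	1
n025	n035	1
n031	n035	1
n032	n035	1
n033	n035	1
n034	n035	1
n001	n036	1
n025	n036	1
n026	n036	1
n028	n036	1
n031	n036	1
n034	n036	1
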