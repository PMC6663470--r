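node_id	class	label
n001	sensory	n001
n002	sensory	n002
n003	sensory	n003
n004	sensory	n004
n005	sensory	n005
n006	sensory	n006
n007	sensory	n007
n008	sensory	n008
n009	sensory	n009
n010	sensory	n010
n011	sensory	n011
n012	sensory	n012
n013	inter	n013
n014	inter	n014
n015	inter	n015
n016	inter	n016
n017	inter	n017
n018	inter	n018
n019	inter	n019
n020	inter	n020
n021	inter	n021
n022	inter	n022
n023	inter	n023
n024	inter	n024
n025	motor	n025
n026	motor	n026
n027	motor	n027
n028	motor	n028
n029	motor	n029
n030	motor	n030
n031	motor	n031
n032	motor	n032
n033	motor	n033
n034	motor	n034
n035	motor	n035
n036	motor	n036
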