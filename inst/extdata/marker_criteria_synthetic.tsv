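state	gene	level
ESC	g0001	Hi
ESC	g0002	Hi
ESC	g0003	Hi
ESC	g0004	Hi
ESC	g0005	Hi
ESC	g0021	Absent
ESC	g0022	Absent
ESC	g0023	Absent
ESC	g0024	Absent
ESC	g0025	Absent
ESC	g0041	Absent
ESC	g0042	Absent
ESC	g0043	Absent
ESC	g0044	Absent
ESC	g0045	Absent
ESC	g0061	Absent
ESC	g0062	Absent
ESC	g0063	Absent
ESC	g0064	Absent
ESC	g0065	Absent
ESC	g0081	Absent
ESC	g0082	Absent
ESC	g0083	Absent
ESC	g0084	Absent
ESC	g0085	Absent
ESC	g0101	Absent
ESC	g0102	Absent
ESC	g0103	Absent
ESC	g0104	Absent
ESC	g0105	Absent
NP	g0021	Hi
NP	g0022	Hi
NP	g0023	Hi
NP	g0024	Hi
NP	g0025	Hi
NP	g0001	Absent
NP	g0002	Absent
NP	g0003	Absent
NP	g0004	Absent
NP	g0005	Absent
NP	g0041	Absent
NP	g0042	Absent
NP	g0043	Absent
NP	g0044	Absent
NP	g0045	Absent
NP	g0061	Absent
NP	g0062	Absent
NP	g0063	Absent
NP	g0064	Absent
NP	g0065	Absent
NP	g0081	Absent
NP	g0082	Absent
NP	g0083	Absent
NP	g0084	Absent
NP	g0085	Absent
NP	g0101	Absent
NP	g0102	Absent
NP	g0103	Absent
NP	g0104	Absent
NP	g0105	Absent
EMN	g0041	Hi
EMN	g0042	Hi
EMN	g0043	Hi
EMN	g0044	Hi
EMN	g0045	Hi
EMN	g0001	Absent
EMN	g0002	Absent
EMN	g0003	Absent
EMN	g0004	Absent
EMN	g0005	Absent
EMN	g0021	Absent
EMN	g0022	Absent
EMN	g0023	Absent
EMN	g0024	Absent
EMN	g0025	Absent
EMN	g0061	Absent
EMN	g0062	Absent
EMN	g0063	Absent
EMN	g0064	Absent
EMN	g0065	Absent
EMN	g0081	Absent
EMN	g0082	Absent
EMN	g0083	Absent
EMN	g0084	Absent
EMN	g0085	Absent
EMN	g0101	Absent
EMN	g0102	Absent
EMN	g0103	Absent
EMN	g0104	Absent
EMN	g0105	Absent
LMN	g0061	Hi
LMN	g0062	Hi
LMN	g0063	Hi
LMN	g0064	Hi
LMN	g0065	Hi
LMN	g0001	Absent
LMN	g0002	Absent
LMN	g0003	Absent
LMN	g0004	Absent
LMN	g0005	Absent
LMN	g0021	Absent
LMN	g0022	Absent
LMN	g0023	Absent
LMN	g0024	Absent
LMN	g0025	Absent
LMN	g0041	Absent
LMN	g0042	Absent
LMN	g0043	Absent
LMN	g0044	Absent
LMN	g0045	Absent
LMN	g0081	Absent
LMN	g0082	Absent
LMN	g0083	Absent
LMN	g0084	Absent
LMN	g0085	Absent
LMN	g0101	Absent
LMN	g0102	Absent
LMN	g0103	Absent
LMN	g0104	Absent
LMN	g0105	Absent
PVNP	g0081	Hi
PVNP	g0082	Hi
PVNP	g0083	Hi
PVNP	g0084	Hi
PVNP	g0085	Hi
PVNP	g0001	Absent
PVNP	g0002	Absent
PVNP	g0003	Absent
PVNP	g0004	Absent
PVNP	g0005	Absent
PVNP	g0021	Absent
PVNP	g0022	Absent
PVNP	g0023	Absent
PVNP	g0024	Absent
PVNP	g0025	Absent
PVNP	g0041	Absent
PVNP	g0042	Absent
PVNP	g0043	Absent
PVNP	g0044	Absent
PVNP	g0045	Absent
PVNP	g0061	Absent
PVNP	g0062	Absent
PVNP	g0063	Absent
PVNP	g0064	Absent
PVNP	g0065	Absent
PVNP	g0101	Absent
PVNP	g0102	Absent
PVNP	g0103	Absent
PVNP	g0104	Absent
PVNP	g0105	Absent
MNP	g0101	Hi
MNP	g0102	Hi
MNP	g0103	Hi
MNP	g0104	Hi
MNP	g0105	Hi
MNP	g0001	Absent
MNP	g0002	Absent
MNP	g0003	Absent
MNP	g0004	Absent
MNP	g0005	Absent
MNP	g0021	Absent
MNP	g0022	Absent
MNP	g0023	Absent
MNP	g0024	Absent
MNP	g0025	Absent
MNP	g0041	Absent
MNP	g0042	Absent
MNP	g0043	Absent
MNP	g0044	Absent
MNP	g0045	Absent
MNP	g0061	Absent
MNP	g0062	Absent
MNP	g0063	Absent
MNP	g0064	Absent
MNP	g0065	Absent
MNP	g0081	Absent
MNP	g0082	Absent
MNP	g0083	Absent
MNP	g0084	Absent
MNP	g0085	Absent
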