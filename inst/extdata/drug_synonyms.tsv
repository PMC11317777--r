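canonical_drug	synonym
DOXYCYCLINE	DOXYCYCLINE
DOXYCYCLINE	DOXYCYCLINE HYCLATE
DOXYCYCLINE	DOXYCYCLINE MONOHYDRATE
DOXYCYCLINE	DOXYCYCLINE CALCIUM
DOXYCYCLINE	DOXYCYCLINE HYCLATE DR
DOXYCYCLINE	VIBRAMYCIN
DOXYCYCLINE	DORYX
DOXYCYCLINE	ORACEA
DOXYCYCLINE	MONODOX
DOXYCYCLINE	ACTICLATE
DOXYCYCLINE	ADOXA
DOXYCYCLINE	PERIOSTAT
DOXYCYCLINE	TARGADOX
DOXYCYCLINE	VIBRA-TABS
DOXYCYCLINE	DOXY 100
DOXYCYCLINE	ATRIDOX
MINOCYCLINE	MINOCYCLINE
MINOCYCLINE	MINOCYCLINE HYDROCHLORIDE
MINOCYCLINE	MINOCIN
MINOCYCLINE	SOLODYN
MINOCYCLINE	DYNACIN
MINOCYCLINE	XIMINO
MINOCYCLINE	MINOLIRA
MINOCYCLINE	AMZEEQ
MINOCYCLINE	ARESTIN
MINOCYCLINE	ZILXI
TIGECYCLINE	TIGECYCLINE
TIGECYCLINE	TYGACIL
TIGECYCLINE	GAR-936
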