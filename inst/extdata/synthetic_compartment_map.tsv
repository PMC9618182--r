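id	compartment	fine
SNAP25	presynaptic	synaptic vesicle
SYP	presynaptic	synaptic vesicle
STX1A	presynaptic	active zone
UNC13A	presynaptic	active zone
RAB3A	presynaptic	synaptic vesicle
SYT1	presynaptic	synaptic vesicle
DLG4	postsynaptic	postsynaptic density
SYNPO	postsynaptic	spine apparatus
SHANK2	postsynaptic	postsynaptic density
SHANK3	postsynaptic	postsynaptic density
HOMER1	postsynaptic	postsynaptic density
GRIA1	postsynaptic	postsynaptic membrane
GRIN1	postsynaptic	postsynaptic membrane
SYNGAP1	postsynaptic	postsynaptic density
FRMPD4	postsynaptic	postsynaptic density
ACTB	both	cytoskeleton
CAMK2A	both	cytoskeleton
NRXN1	presynaptic	adhesion
NLGN1	postsynaptic	adhesion
CDH7	both	adhesion
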