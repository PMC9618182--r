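glutamatergic_synapse	synthetic demo set	SP00001	SP00002	SP00003	SP00004	SP00005	SP00006
complement_cascade	synthetic demo set	SP00007	SP00008	SP00009	SP00010
vesicle_trafficking	synthetic demo set	SP00011	SP00012	SP00013	SP00014	SP00015	SP00016	SP00017
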