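# synthetic synapse reference list (accessions; illustrative fixture)
SP00001
SP00002
SP00003
SP00004
SP00005
SP00006
SP00007
SP00008
SP00010
SP00011
SP00012
SP00013
SP00014
SP00015
SP00016
SP00018
SP00019
SP00020
SP00021
SP00022
SP00023
SP00024
SP00025
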