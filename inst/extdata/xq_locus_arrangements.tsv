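# Signed synteny-block arrangements of the Y-derived insertion locus on
# distal Xq in the two Y-less spiny rat species. Block order follows the
# boundary-duplication adjacencies reported for each species; orientations
# are this package's reading of the cross-species alignment. SB5p is the
# duplicated portion of SB5 and is excluded before distance computation.
species	arrangement
T_osimensis	SB1+ SB6+ SB5- SB2- SB5p- SB3+ SB4+
T_tokunoshimensis	SB1+ SB3- SB5p- SB5- SB2+ SB6+ SB4+
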