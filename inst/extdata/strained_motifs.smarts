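# Strained ring motifs removed by the structural filter.
# One pattern per line: SMARTS whitespace label. Lines starting with '#' are
# comments. The list is a curated package default, conservative by design:
# it targets motifs that are almost always unmakeable at ambient conditions.
# Edit or extend freely; strained_motif_filter() reads this file at run time.
[C;x3;r3,r4,r5]=[C] bridgehead or small-ring-junction alkene (anti-Bredt)
[#6;r3,r4,r5,r6,r7]#[#6] triple bond inside a ring of 7 or fewer atoms
C=[C;r3,r4,r5,r6]=C cumulated diene centered in a small ring
[C;x3;r3]@[C;x3;r3] fused cyclopropane stack (bicyclobutane-like)
[#6;r3]=[#8,#7] exocyclic-heteroatom double bond on a three-membered ring
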